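#' Run the full analysis pipeline on simulated inputs
#'
#' End-to-end orchestration in dependency order: simulate inputs, compile
#' the non-redundant region set (merge + coding filter), annotate context
#' and gene proximity, term enrichment, peak/state overlap, train the
#' enhancer classifier and predict on the compiled regions, TFBS
#' divergence, candidate prioritization and the packaged validation
#' cohort.  Every stage's outputs are written under \code{out_dir} and
#' recorded, with md5 checksums, in \code{manifest.json}; reruns with
#' the same config give identical checksums.
#'
#' @param config a \code{\link{sim_config}} (or a YAML path / list of
#'   its arguments, which must include \code{seed}).
#' @param out_dir output directory, created if needed.
#' @param n_perm permutations for the divergence test.
#' @param n_candidates candidates to select.
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ncharlab_run_"),
                         n_perm = 199, n_candidates = 10) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(obj, file, writer) {
    p <- file.path(out_dir, file)
    writer(obj, p)
    paths[[file]] <<- p
    p
  }

  # -- simulate ------------------------------------------------------
  genome <- simulate_genome(config)
  ann <- simulate_annotations(config, genome)
  planted <- plant_enhancers(config)
  emit(ann$terms, "terms.gmt", write_gmt)
  for (nm in names(ann$sets))
    emit(ann$sets[[nm]], paste0(nm, ".bed"), write_regions)

  # -- compile -------------------------------------------------------
  merged <- merge_region_sets(ann$sets, prefix = "nchar")
  compiled <- filter_coding(merged, ann$genes)
  emit(compiled, "nchars.bed", write_regions)

  # a fraction of the compiled regions carry a genuine planted enhancer
  # signature (sequence sites + context-matched marks)
  gp <- plant_genome_enhancers(config, genome, compiled, planted$vocab)
  genome <- gp$genome
  emit(genome, "genome.fa",
       function(o, p) Biostrings::writeXStringSet(o, p))
  context <- classify_context(compiled, ann$genes)
  tssi <- tss_index(ann$genes)
  summary_rec <- summarize_regions(compiled, ann$genes, tssi)

  # -- enrichment ----------------------------------------------------
  domains <- build_regulatory_domains(
    ann$genes, chrom_lengths = vapply(genome, length, 0L))
  enr <- term_enrichment(compiled, domains, ann$terms,
                         background = "whole_genome",
                         genome_size = sum(config$chrom_lengths))
  emit(enr, "enrichment.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # -- classifier ----------------------------------------------------
  el <- planted$elements
  blocks <- featurize(el$seqs, marks = planted$marks)
  model <- enhancer_finder(blocks, el$labels, tissues = el$tissues,
                           seed = config$seed)
  windows <- extract_window(compiled, width = config$element_len,
                            chrom_lengths = vapply(genome, length, 0L))
  wseqs <- window_seqs(genome, windows)
  pred <- predict(model, featurize(wseqs, marks = gp$marks))
  pred <- cbind(region_id = compiled$name, pred)
  emit(pred, "predictions.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # -- tfbs divergence ----------------------------------------------
  div <- tfbs_divergence(planted$pairs, planted$pwms[1:4],
                         n_perm = n_perm, seed = config$seed)
  div_sum <- summarize_divergence(div)
  emit(div, "tfbs_divergence.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # -- prioritization ------------------------------------------------
  n_rank <- min(nrow(pred), length(planted$pairs))
  ctx <- data.frame(
    region_id = pred$region_id[seq_len(n_rank)],
    dev_gene_within_1mb = vapply(
      genes_within(compiled[seq_len(n_rank), ], ann$genes),
      function(ids) any(ids %in% ann$truth$tagged$developmental), TRUE),
    tf_nearest = nearest_gene(compiled[seq_len(n_rank), ], ann$genes) %in%
      ann$truth$tagged$TF,
    de_gene_within_1mb = vapply(
      genes_within(compiled[seq_len(n_rank), ], ann$genes),
      function(ids) any(ids %in% ann$truth$tagged$diff_expressed), TRUE))
  div_counts <- data.frame(
    region_id = ctx$region_id,
    n_sig_tfs = as.vector(div_sum$per_region)[seq_len(n_rank)])
  scores <- score_candidates(pred[seq_len(n_rank), ], div_counts, ctx)
  sel <- select_top(scores, n = min(n_candidates, nrow(scores)))
  emit(sel, "candidates.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # -- validation (packaged cohort) ---------------------------------
  calls <- load_assay_calls()
  results <- analyze_assays(calls)
  cohort <- summarize_cohort(results, load_construct_predictions(),
                             load_validation_ledger())
  emit(results, "validation_calls.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ncharlab")),
    seed = config$seed,
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = out_dir, compiled = compiled,
                 planted_truth = gp$truth,
                 context = context, summary = summary_rec,
                 enrichment = enr, model = model, predictions = pred,
                 divergence = div, divergence_summary = div_sum,
                 candidates = sel, validation = results, cohort = cohort,
                 manifest = manifest))
}
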