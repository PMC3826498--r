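## Synthetic-data generators.  Every input the pipeline consumes can be
## produced here with planted ground truth, so all downstream stages are
## testable offline: a toy genome, gene models with tags and terms,
## accelerated-region interval sets sampled from conserved elements,
## motif-bearing training elements with enhancer-mark peaks, ortholog
## pairs with planted substitutions, and noisy embryo staining tables.

#' Simulation configuration
#'
#' Collects the tunable parameters of the synthetic-data generators with
#' their defaults.  Interval-length parameters default to the published
#' ncHAR cohort moments (mean 257 bp, sd 171 bp).
#'
#' @param seed mandatory integer seed; all generator randomness derives
#'   from it.
#' @param chrom_lengths named vector of toy chromosome lengths (>= 10 kb
#'   each).
#' @param base_freqs background base frequencies (A, C, G, T).
#' @param n_genes number of genes to place.
#' @param tf_frac,dev_frac,de_frac fractions of genes tagged TF /
#'   developmental / differentially expressed.
#' @param n_terms,genes_per_term term annotation sizes.
#' @param n_conserved number of conserved non-coding elements.
#' @param mean_len,sd_len conserved-element length moments (bp).
#' @param n_sets number of accelerated-region sets.
#' @param set_size regions per accelerated set.
#' @param set_overlap expected fraction of a set's regions shared with
#'   the previously drawn set.
#' @param element_len training-element window length (bp).
#' @param n_pos,n_neg planted-enhancer training-set sizes.
#' @param motifs_per_tissue,motif_width,sites_per_element motif
#'   vocabulary geometry for planted enhancers.
#' @param site_fidelity per-base probability that a planted site carries
#'   the consensus base (functional sites are near-consensus instances).
#' @param mark_rate_pos,mark_rate_neg per-mark peak probability around
#'   planted enhancers vs background elements.
#' @param genome_enhancer_frac fraction of compiled regions that carry a
#'   planted enhancer signature in the simulated genome (~0.3, matching
#'   the scale of enhancer prevalence estimated for accelerated regions).
#' @param n_subs substitutions applied per ortholog pair.
#' @param sub_target_frac fraction of pairs whose substitutions are
#'   aimed at a planted motif site.
#' @param n_embryos embryos per construct and species.
#' @param call_noise per-domain staining flip probability.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chrA = 100000L, chrB = 100000L),
                       base_freqs = rep(0.25, 4),
                       n_genes = 30, tf_frac = 0.15, dev_frac = 0.3,
                       de_frac = 0.3,
                       n_terms = 10, genes_per_term = 6,
                       n_conserved = 300, mean_len = 257, sd_len = 171,
                       n_sets = 4, set_size = 60, set_overlap = 0.3,
                       element_len = 1500, n_pos = 400, n_neg = 400,
                       motifs_per_tissue = 2, motif_width = 8,
                       sites_per_element = 8, site_fidelity = 0.95,
                       mark_rate_pos = 0.8, mark_rate_neg = 0.1,
                       genome_enhancer_frac = 0.3,
                       n_subs = 10, sub_target_frac = 0.5,
                       n_embryos = 4, call_noise = 0) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(chrom_lengths < 10000)) stop("chromosome lengths must be >= 10 kb")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = freqs / sum(freqs)), collapse = "")
}

#' Simulate a toy genome
#'
#' i.i.d. bases at the configured frequencies, one sequence per
#' chromosome; fully determined by the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return named \code{DNAStringSet}.
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, {
    seqs <- vapply(config$chrom_lengths, random_dna, "",
                   freqs = config$base_freqs)
    Biostrings::DNAStringSet(setNames(seqs, names(config$chrom_lengths)))
  })
}

## sample interval lengths at the configured moments (truncated normal)
rlengths <- function(n, mean_len, sd_len, min_len = 20) {
  pmax(min_len, round(stats::rnorm(n, mean_len, sd_len)))
}

#' Simulate gene models, terms, conserved elements and accelerated sets
#'
#' Gene models are non-pathological (3 exons, coding middle exon for
#' protein-coding genes, both strands, a mix of gene types); accelerated
#' sets are built by sampling conserved elements with the configured
#' inter-set overlap so that merge and coding-filter paths are
#' exercised.  Ground truth (tag assignments, shared-element identities)
#' is returned alongside.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome output of \code{\link{simulate_genome}} (used for
#'   chromosome names/lengths only).
#' @return list: \code{genes} (a \code{gene_models}), \code{terms},
#'   \code{conserved} (a \code{region_set}), \code{sets} (list of
#'   \code{region_set}s), \code{truth}.
#' @export
simulate_annotations <- function(config, genome) {
  lens <- vapply(genome, length, 0L)
  with_seed(config$seed + 1L, {
    n <- config$n_genes
    chrom <- sample(names(lens), n, replace = TRUE)
    glen <- pmin(sample(3000:8000, n, replace = TRUE),
                 lens[chrom] %/% 4L)
    start <- vapply(seq_len(n), function(i)
      sample.int(lens[chrom[i]] - glen[i], 1) - 1L, 0L)
    types <- sample(c("protein_coding", "pseudogene", "lincRNA", "miRNA"),
                    n, replace = TRUE, prob = c(0.7, 0.1, 0.15, 0.05))
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(n)),
      chrom = chrom, strand = sample(c("+", "-"), n, TRUE),
      start = start, end = start + glen, gene_type = types,
      stringsAsFactors = FALSE)
    # three exons; middle exon carries the CDS for protein-coding genes
    exons <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- seq(genes$start[i], genes$end[i], length.out = 7)
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = as.integer(b[c(1, 3, 5)]),
                 end = as.integer(b[c(2, 4, 6)]),
                 is_coding = c(FALSE,
                               genes$gene_type[i] == "protein_coding",
                               FALSE),
                 stringsAsFactors = FALSE)
    }))
    gm <- gene_models(genes, exons)
    tagged <- list()
    for (tg in c("TF", "developmental", "diff_expressed")) {
      frac <- switch(tg, TF = config$tf_frac,
                     developmental = config$dev_frac, config$de_frac)
      ids <- sample(genes$gene_id, round(frac * n))
      gm <- tag_genes(gm, ids, tg)
      tagged[[tg]] <- ids
    }
    terms <- lapply(seq_len(config$n_terms), function(i)
      sample(genes$gene_id, min(config$genes_per_term, n)))
    names(terms) <- sprintf("T%03d", seq_len(config$n_terms))
    # conserved elements, avoiding coding exons
    cod <- exons[exons$is_coding, , drop = FALSE]
    m <- config$n_conserved
    clen <- rlengths(m, config$mean_len, config$sd_len)
    cchrom <- sample(names(lens), m, replace = TRUE)
    cstart <- vapply(seq_len(m), function(i)
      sample.int(lens[cchrom[i]] - clen[i], 1) - 1L, 0L)
    cons <- data.frame(chrom = cchrom, start = cstart,
                       end = cstart + clen)
    keep <- !overlaps_any(cons, cod)
    cons <- cons[keep, , drop = FALSE]
    # conserved elements are kept mutually disjoint (drop later starters
    # that touch the previous element on the same chromosome)
    cons <- cons[order(cons$chrom, cons$start), , drop = FALSE]
    ok <- unlist(lapply(split(seq_len(nrow(cons)), cons$chrom),
                        function(ix) {
      keep <- logical(length(ix)); last_end <- -1L
      for (j in seq_along(ix)) {
        if (cons$start[ix[j]] > last_end) {
          keep[j] <- TRUE
          last_end <- cons$end[ix[j]]
        }
      }
      ix[keep]
    }))
    cons <- cons[sort(ok), , drop = FALSE]
    conserved <- region_set(cons$chrom, cons$start, cons$end,
                            name = sprintf("cons_%d", seq_len(nrow(cons))),
                            sources = "conserved", genome_id = "toy")
    # accelerated sets: each reuses a fraction of the previous set's
    # elements and samples the rest fresh from untouched conserved
    # elements, so the realized inter-set overlap is exactly the shared
    # draw
    sets <- list()
    prev <- integer(); used <- integer()
    for (s in seq_len(config$n_sets)) {
      k <- min(config$set_size, nrow(conserved))
      n_shared <- if (length(prev)) rbinom(1, k, config$set_overlap) else 0L
      shared <- if (n_shared) sample(prev, min(n_shared, length(prev)))
                else integer()
      pool <- setdiff(seq_len(nrow(conserved)), used)
      fresh <- sample(pool, min(k - length(shared), length(pool)))
      idx <- sort(c(shared, fresh))
      used <- union(used, idx)
      sets[[paste0("set", s)]] <- region_set(
        conserved$chrom[idx], conserved$start[idx], conserved$end[idx],
        name = conserved$name[idx], sources = paste0("set", s),
        genome_id = "toy")
      prev <- idx
    }
    list(genes = gm, terms = terms, conserved = conserved, sets = sets,
         truth = list(tagged = tagged))
  })
}

random_pwm <- function(width, info = 0.85) {
  m <- matrix((1 - info) / 3, width, 4)
  dom <- sample.int(4, width, replace = TRUE)
  m[cbind(seq_len(width), dom)] <- info
  m
}

## planted sites are near-consensus instances: functional binding sites
## are high-affinity draws from the motif, not typical PWM samples
sample_site <- function(p, fidelity = 0.95) {
  cons <- apply(p$prob, 1, which.max)
  base <- vapply(seq_len(p$width), function(i) {
    if (stats::runif(1) < fidelity) cons[i]
    else sample(setdiff(1:4, cons[i]), 1)
  }, 0L)
  paste(c("A", "C", "G", "T")[base], collapse = "")
}

insert_at <- function(seq, site, pos0) {
  paste0(substr(seq, 1, pos0), site,
         substr(seq, pos0 + nchar(site) + 1, nchar(seq)))
}

#' Plant enhancer training data, peaks and ortholog pairs
#'
#' Positives receive \code{sites_per_element} inserted instances of
#' their tissue's motifs and elevated per-mark peak probability;
#' negatives are background sequence.  Ortholog pairs are derived by
#' applying \code{n_subs} substitutions to a "chimp" sequence carrying
#' one perfect planted site; for a configured fraction of pairs one
#' substitution is aimed into the planted site (a binding-site loss on
#' the human branch).  Full ground truth is returned.
#'
#' @param config a \code{\link{sim_config}}.
#' @param tissues tissues to build vocabularies for.
#' @return list: \code{elements} (sequences, labels, tissue lists),
#'   \code{marks} (0/1 matrix), \code{pwms} (per-tissue vocabularies,
#'   flattened list), \code{pairs} (list of \code{ortholog_pair}),
#'   \code{truth}.
#' @export
plant_enhancers <- function(config, tissues = TISSUES) {
  with_seed(config$seed + 2L, {
    vocab <- lapply(setNames(tissues, tissues), function(t)
      lapply(seq_len(config$motifs_per_tissue), function(i)
        pwm(random_pwm(config$motif_width),
            tf_id = sprintf("%s_m%d", t, i))))
    n_pos <- config$n_pos; n_neg <- config$n_neg
    L <- config$element_len
    tis_assign <- rep_len(tissues, n_pos)
    seqs <- character(n_pos + n_neg)
    site_truth <- vector("list", n_pos + n_neg)
    for (i in seq_len(n_pos)) {
      s <- random_dna(L, config$base_freqs)
      pws <- vocab[[tis_assign[i]]]
      pos_used <- integer()
      for (j in seq_len(config$sites_per_element)) {
        repeat {
          p0 <- sample.int(L - config$motif_width, 1) - 1L
          if (!any(abs(p0 - pos_used) < config$motif_width)) break
        }
        pos_used <- c(pos_used, p0)
        s <- insert_at(s, sample_site(pws[[1 + (j - 1) %% length(pws)]],
                                      config$site_fidelity), p0)
      }
      seqs[i] <- s
      site_truth[[i]] <- sort(pos_used)
    }
    for (i in seq_len(n_neg))
      seqs[n_pos + i] <- random_dna(L, config$base_freqs)
    labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
    tissue_lists <- c(lapply(tis_assign, identity),
                      replicate(n_neg, character(), simplify = FALSE))
    # enhancer marks are simulated per cellular context (one context per
    # tissue): a positive is peak-enriched in the context matching its
    # tissue and at background rate elsewhere, mirroring how tissue
    # information enters real functional-genomics compendia
    mark_names <- c("H3K4me1", "H3K27ac", "P300")
    el_tissue <- c(tis_assign, rep(NA_character_, n_neg))
    marks <- do.call(cbind, lapply(tissues, function(ctx) {
      rate <- ifelse(!is.na(el_tissue) & el_tissue == ctx,
                     config$mark_rate_pos, config$mark_rate_neg)
      m <- vapply(mark_names, function(mk)
        rbinom(n_pos + n_neg, 1, rate), numeric(n_pos + n_neg))
      colnames(m) <- paste(mark_names, ctx, sep = ".")
      m
    }))
    names(seqs) <- sprintf("el_%03d", seq_along(seqs))
    # ortholog pairs with one planted site; losses in a known fraction
    all_pwms <- unlist(vocab, recursive = FALSE)
    n_pairs <- min(50L, n_pos)
    pair_len <- 200L
    pairs <- vector("list", n_pairs)
    loss <- logical(n_pairs)
    pair_tf <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      p <- all_pwms[[1 + (i - 1) %% length(all_pwms)]]
      site <- paste(c("A", "C", "G", "T")[apply(p$prob, 1, which.max)],
                    collapse = "")
      s0 <- sample.int(pair_len - p$width, 1) - 1L
      chimp <- insert_at(random_dna(pair_len, config$base_freqs), site, s0)
      loss[i] <- config$n_subs > 0 && runif(1) < config$sub_target_frac
      pair_tf[i] <- p$tf_id
      cc <- strsplit(chimp, "")[[1]]
      hh <- cc
      spots <- if (config$n_subs == 0) integer()
      else if (loss[i])
        c(s0 + sample.int(p$width, 1),
          sample(setdiff(seq_len(pair_len), (s0 + 1):(s0 + p$width)),
                 config$n_subs - 1L))
      else sample(setdiff(seq_len(pair_len), (s0 + 1):(s0 + p$width)),
                  config$n_subs)
      for (sp in spots)
        hh[sp] <- sample(setdiff(c("A", "C", "G", "T"), cc[sp]), 1)
      pairs[[i]] <- ortholog_pair(sprintf("pair_%03d", i),
                                  paste(hh, collapse = ""), chimp)
    }
    list(elements = list(seqs = seqs, labels = labels,
                         tissues = tissue_lists),
         marks = marks, pwms = all_pwms, vocab = vocab, pairs = pairs,
         truth = list(tissue = tis_assign, sites = site_truth,
                      pair_loss = loss, pair_tf = pair_tf))
  })
}

#' Plant enhancer signatures into a simulated genome
#'
#' Chooses a fraction of the given regions, assigns each a tissue, and
#' writes \code{sites_per_element} near-consensus instances of that
#' tissue's motifs into the genome around the region midpoint.  Also
#' simulates a per-region evidence matrix: planted regions are
#' peak-enriched in their tissue's cellular context (rate
#' \code{mark_rate_pos}), everything else at background rate.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome named \code{DNAStringSet}; returned modified.
#' @param regions a \code{region_set} (e.g. the compiled set).
#' @param vocab per-tissue PWM vocabularies
#'   (\code{plant_enhancers()$vocab}).
#' @return list: \code{genome} (modified), \code{marks} (0/1 matrix, one
#'   row per region), \code{truth} (data frame \code{name},
#'   \code{is_enhancer}, \code{tissue}).
#' @export
plant_genome_enhancers <- function(config, genome, regions, vocab) {
  with_seed(config$seed + 5L, {
    n <- nrow(regions)
    planted <- sort(sample.int(n, round(config$genome_enhancer_frac * n)))
    tissue <- rep(NA_character_, n)
    tissue[planted] <- sample(names(vocab), length(planted), replace = TRUE)
    seqs <- as.character(genome)
    w <- config$motif_width
    for (i in planted) {
      chr <- regions$chrom[i]
      mid <- (regions$start[i] + regions$end[i]) %/% 2L
      pws <- vocab[[tissue[i]]]
      offs <- seq(-config$sites_per_element %/% 2L,
                  length.out = config$sites_per_element) * (w + 4L)
      for (j in seq_along(offs)) {
        p0 <- mid + offs[j]
        if (p0 < 0 || p0 + w > nchar(seqs[[chr]])) next
        seqs[[chr]] <- insert_at(seqs[[chr]],
                                 sample_site(pws[[1 + (j - 1) %%
                                                    length(pws)]],
                                             config$site_fidelity), p0)
      }
    }
    mark_names <- c("H3K4me1", "H3K27ac", "P300")
    marks <- do.call(cbind, lapply(names(vocab), function(ctx) {
      rate <- ifelse(!is.na(tissue) & tissue == ctx,
                     config$mark_rate_pos, config$mark_rate_neg)
      m <- vapply(mark_names, function(mk) rbinom(n, 1, rate), numeric(n))
      colnames(m) <- paste(mark_names, ctx, sep = ".")
      m
    }))
    rownames(marks) <- regions$name
    list(genome = Biostrings::DNAStringSet(seqs),
         marks = marks,
         truth = data.frame(name = regions$name,
                            is_enhancer = !is.na(tissue),
                            tissue = tissue, stringsAsFactors = FALSE))
  })
}

#' Simulate per-embryo staining calls from construct truth
#'
#' Truth rows name the active (construct, species, domain) combinations;
#' \code{pattern_id} may be a single label or a \code{|}-separated cycle
#' assigned across embryos (to emulate within-domain pattern
#' variability).  Each embryo's staining in each vocabulary domain is
#' the truth flipped independently with probability \code{noise}.  With
#' \code{noise = 0} the calls equal the truth for every embryo.
#'
#' @param truth data frame: \code{construct_id}, \code{species},
#'   \code{domain}, \code{pattern_id}; constructs absent from it are
#'   fully inactive but must be listed in \code{constructs}.
#' @param constructs character vector of all construct ids.
#' @param n_embryos embryos per construct and species.
#' @param noise per-domain flip probability.
#' @param seed RNG seed.
#' @return embryo-call data frame (see \code{\link{read_embryo_calls}}).
#' @export
simulate_embryo_calls <- function(truth, constructs = unique(truth$construct_id),
                                  n_embryos = 4, noise = 0, seed = 1) {
  with_seed(seed, {
    rows <- list()
    for (cid in constructs) {
      for (sp in c("human", "chimp")) {
        tr <- truth[truth$construct_id == cid & truth$species == sp, ,
                    drop = FALSE]
        for (e in seq_len(n_embryos)) {
          eid <- sprintf("%s_%s_e%d", cid, substr(sp, 1, 1), e)
          any_row <- FALSE
          for (d in DOMAIN_VOCAB) {
            on <- d %in% tr$domain
            if (noise > 0 && runif(1) < noise) on <- !on
            if (on) {
              pat <- tr$pattern_id[tr$domain == d]
              pat <- if (length(pat) && !is.na(pat[1])) {
                cyc <- strsplit(pat[1], "|", fixed = TRUE)[[1]]
                cyc[1 + (e - 1) %% length(cyc)]
              } else "p1"
              rows[[length(rows) + 1]] <- data.frame(
                construct_id = cid, species = sp, embryo_id = eid,
                domain = d, staining = "stained", pattern_id = pat,
                stringsAsFactors = FALSE)
              any_row <- TRUE
            }
          }
          if (!any_row)
            rows[[length(rows) + 1]] <- data.frame(
              construct_id = cid, species = sp, embryo_id = eid,
              domain = "other", staining = "none",
              pattern_id = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Truth table of the packaged 29-construct assay cohort
#'
#' Encodes, as (construct, species, domain, pattern) activity rows plus
#' a prediction table, a 29-construct transgenic cohort with 24 active
#' constructs (17 with reproducible within-domain patterns, 5 of those
#' with a species difference in a high-confidence domain) and 16
#' constructs active in a predicted tissue.  Per-embryo composition is
#' synthetic: only the cohort-level counts follow the published assay
#' summary.
#'
#' @return list: \code{truth} (activity rows for
#'   \code{\link{simulate_embryo_calls}}), \code{constructs},
#'   \code{predictions}.
#' @export
assay_cohort_truth <- function() {
  constructs <- sprintf("c%02d", 1:29)
  both <- function(cid, domain, pattern = "p1")
    data.frame(construct_id = cid, species = c("human", "chimp"),
               domain = domain, pattern_id = pattern,
               stringsAsFactors = FALSE)
  rows <- list()
  # c01-c05: active forebrain both species; midbrain human-only
  # (species difference in a high-confidence domain)
  for (cid in sprintf("c%02d", 1:5)) {
    rows[[length(rows) + 1]] <- both(cid, "forebrain")
    rows[[length(rows) + 1]] <- data.frame(
      construct_id = cid, species = "human", domain = "midbrain",
      pattern_id = "p1", stringsAsFactors = FALSE)
  }
  # c06-c13: consistent forebrain activity, no difference
  for (cid in sprintf("c%02d", 6:13))
    rows[[length(rows) + 1]] <- both(cid, "forebrain")
  # c14-c16: consistent limb activity (predicted limb)
  for (cid in sprintf("c%02d", 14:16))
    rows[[length(rows) + 1]] <- both(cid, "limb")
  # c17: consistent eye activity (limb predicted, no tissue match)
  rows[[length(rows) + 1]] <- both("c17", "eye")
  # c18-c21: limb-predicted, active in eye with embryo-varying patterns
  for (cid in sprintf("c%02d", 18:21))
    rows[[length(rows) + 1]] <- both(cid, "eye", pattern = "pA|pB|pC|pD")
  # c22-c24: neural-tube predicted, active facial mesenchyme, varying
  for (cid in sprintf("c%02d", 22:24))
    rows[[length(rows) + 1]] <- both(cid, "facial_mesenchyme",
                                     pattern = "pA|pB|pC|pD")
  truth <- do.call(rbind, rows)
  predictions <- data.frame(
    construct_id = constructs,
    predicted_tissues = c(
      paste0("brain", c(rep(",neural_tube", 4), rep(",heart", 4),
                        rep(",other", 3), "", "")),       # c01-c13
      rep("limb", 8),                                     # c14-c21
      rep("neural_tube", 3),                              # c22-c24
      rep("other", 5)),                                   # c25-c29
    stringsAsFactors = FALSE)
  list(truth = truth, constructs = constructs, predictions = predictions)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ncharlab")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

FIXTURE_MD5 <- c(
  vista_overlap_enhancers.tsv = "a0d435c0829f53bbbb1bc5881da2d4a3",
  assay_calls_synthetic.tsv = "c3193bc5b3af9be64b3a2b56fdd18c0a",
  construct_predictions_synthetic.tsv = "21617639d0efb8e5a314e33701692519",
  validation_ledger.tsv = "98e2156ff7889560e9fffc26d2b27f68")

check_fixture <- function(file) {
  p <- fixture_path(file)
  if (!identical(unname(tools::md5sum(p)), FIXTURE_MD5[[file]]))
    stop("fixture checksum mismatch: ", file)
  p
}

#' Packaged fixture: ncHARs overlapping validated VISTA enhancers
#'
#' Curated table of 23 ncHARs that coincide with elements shown to drive
#' E11.5 reporter expression in the VISTA Enhancer Browser, with their
#' active tissues and genes within 1 Mb.
#'
#' @return data frame: \code{nchar_id}, \code{vista_id},
#'   \code{active_tissues} (comma-joined), \code{genes_within_1mb},
#'   \code{aliases}.
#' @export
load_vista_overlaps <- function() {
  utils::read.table(check_fixture("vista_overlap_enhancers.tsv"),
                    header = TRUE, sep = "\t", quote = "", fill = TRUE,
                    stringsAsFactors = FALSE, na.strings = "")
}

#' Packaged fixture: per-embryo calls of the 29-construct assay cohort
#'
#' Synthetic per-embryo staining table realizing the cohort truth of
#' \code{\link{assay_cohort_truth}} without noise.
#' @return embryo-call data frame.
#' @export
load_assay_calls <- function() {
  read_embryo_calls(check_fixture("assay_calls_synthetic.tsv"))
}

#' Packaged fixture: predicted tissues of the assay constructs
#' @return data frame \code{construct_id}, \code{predicted_tissues}.
#' @export
load_construct_predictions <- function() {
  utils::read.table(check_fixture("construct_predictions_synthetic.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Packaged fixture: cross-study validation ledger
#'
#' One row per ncHAR tested for developmental enhancer activity across
#' this cohort, the VISTA Enhancer Browser overlaps, and prior targeted
#' studies, deduplicated to the published combined totals.
#'
#' @return data frame \code{construct_id}, \code{source},
#'   \code{outcome}.
#' @export
load_validation_ledger <- function() {
  utils::read.table(check_fixture("validation_ledger.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
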