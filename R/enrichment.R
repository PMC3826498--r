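#' Genes whose TSS lies within a window of each region
#'
#' Distances follow the \code{\link{tss_distance}} convention (region
#' midpoint to TSS); the window boundary is inclusive.
#'
#' @param regions a \code{region_set}.
#' @param genes a \code{gene_models} object.
#' @param window bp; default 1 Mb.
#' @return list (one element per region) of gene_id character vectors.
#' @export
genes_within <- function(regions, genes, window = 1e6) {
  stopifnot(window > 0)
  g <- genes$genes
  mid <- (regions$start + regions$end) %/% 2L
  lapply(seq_len(nrow(regions)), function(i) {
    same <- g$chrom == regions$chrom[i]
    d <- abs(g$tss[same] - mid[i])
    inside <- g$tss[same] >= regions$start[i] & g$tss[same] < regions$end[i]
    g$gene_id[same][d <= window | inside]
  })
}

#' Nearest gene (by TSS) for each region
#'
#' Ties in |distance| are broken towards the lexicographically smaller
#' gene_id.
#'
#' @param regions a \code{region_set}.
#' @param genes a non-empty \code{gene_models} object.
#' @return character vector of gene_ids, one per region (NA when the
#'   region's chromosome carries no TSS).
#' @export
nearest_gene <- function(regions, genes) {
  g <- genes$genes
  if (nrow(g) == 0) stop("empty gene set")
  mid <- (regions$start + regions$end) %/% 2L
  vapply(seq_len(nrow(regions)), function(i) {
    same <- which(g$chrom == regions$chrom[i])
    if (!length(same)) return(NA_character_)
    d <- abs(g$tss[same] - mid[i])
    d[g$tss[same] >= regions$start[i] & g$tss[same] < regions$end[i]] <- 0
    cand <- same[d == min(d)]
    sort(g$gene_id[cand])[1]
  }, "")
}

#' Count regions with a tagged gene nearby
#'
#' @param regions a \code{region_set}.
#' @param genes a \code{gene_models} object with tags assigned.
#' @param tag one of \code{"TF"}, \code{"developmental"},
#'   \code{"diff_expressed"}.
#' @param window bp window around each region midpoint.
#' @return number of regions with at least one gene carrying \code{tag}
#'   whose TSS lies within \code{window}.
#' @export
category_proximity_counts <- function(regions, genes, tag, window = 1e6) {
  if (!tag %in% c("TF", "developmental", "diff_expressed"))
    stop("unknown tag: ", tag)
  tagged <- genes$genes$gene_id[has_tag(genes, tag)]
  if (!length(tagged)) return(0L)
  near <- genes_within(regions, genes, window)
  sum(vapply(near, function(ids) any(ids %in% tagged), TRUE))
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-aware basal window around its TSS
#' (\code{basal_up} upstream, \code{basal_down} downstream), then the
#' window is extended in both directions up to \code{max_ext} from the
#' TSS, stopping early at the nearest neighbouring basal window on the
#' same chromosome.  Domains always contain their own basal window and
#' may overlap neighbouring domains' basal windows.
#'
#' @param genes a \code{gene_models} object.
#' @param basal_up,basal_down bp; defaults 5 kb / 1 kb.
#' @param max_ext maximum extension from the TSS, default 1 Mb.
#' @param chrom_lengths optional named vector used to clip domains.
#' @return data frame: \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{basal_start}, \code{basal_end} (0-based half-open).
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000,
                                     basal_down = 1000, max_ext = 1e6,
                                     chrom_lengths = NULL) {
  g <- genes$genes
  up <- ifelse(g$strand == "+", basal_up, basal_down)
  dn <- ifelse(g$strand == "+", basal_down, basal_up)
  bs <- pmax(0L, g$tss - as.integer(up))
  be <- g$tss + as.integer(dn) + 1L
  ds <- de <- integer(nrow(g))
  for (chr in unique(g$chrom)) {
    i <- which(g$chrom == chr)
    i <- i[order(g$tss[i])]
    for (k in seq_along(i)) {
      j <- i[k]
      lim_lo <- max(0, g$tss[j] - max_ext)
      lim_hi <- g$tss[j] + max_ext
      # stop at neighbouring basal windows (if nearer than max_ext)
      if (k > 1) lim_lo <- max(lim_lo, min(be[i[k - 1]], bs[j]))
      if (k < length(i)) lim_hi <- min(lim_hi, max(bs[i[k + 1]], be[j]))
      ds[j] <- min(bs[j], lim_lo)
      de[j] <- max(be[j], lim_hi)
    }
  }
  if (!is.null(chrom_lengths)) {
    cl <- chrom_lengths[g$chrom]
    de <- pmin(de, as.integer(cl))
    be <- pmin(be, as.integer(cl))
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = as.integer(ds), end = as.integer(de),
             basal_start = bs, basal_end = be, stringsAsFactors = FALSE)
}

#' Read a GMT-style term file
#'
#' One term per line: term_id, term_name, then gene ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors (term_id -> gene ids), with a
#'   \code{term_names} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- vapply(fields, `[`, "", 1L)
  attr(terms, "term_names") <- vapply(fields, `[`, "", 2L)
  terms
}

#' Write terms as GMT
#' @param terms named list of gene-id vectors.
#' @param path output path.
#' @export
write_gmt <- function(terms, path) {
  nm <- attr(terms, "term_names") %||% names(terms)
  lines <- vapply(seq_along(terms), function(i)
    paste(c(names(terms)[i], nm[i], terms[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

## midpoint-in-domain hit test: which regions fall in >=1 domain of `ids`
region_hits_term <- function(regions, domains, ids) {
  d <- domains[domains$gene_id %in% ids, , drop = FALSE]
  if (nrow(d) == 0) return(rep(FALSE, nrow(regions)))
  mid <- (regions$start + regions$end) %/% 2L
  midtab <- data.frame(chrom = regions$chrom, start = mid, end = mid + 1L)
  overlaps_any(midtab, d)
}

## covered-base count of the union of the domains of `ids`
term_coverage <- function(domains, ids) {
  d <- domains[domains$gene_id %in% ids, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end)))
  sum(as.numeric(GenomicRanges::width(gr)))
}

#' Regulatory-domain term enrichment
#'
#' GREAT-style region-based enrichment.  A region "hits" a term when its
#' midpoint falls inside any regulatory domain of a gene annotated with
#' the term.  Against the whole-genome background the p-value is the
#' binomial tail P(X >= k) with n = number of regions and p = fraction of
#' the genome covered by the term's domains.  Against a region-set
#' background (e.g. conserved non-coding elements) it is the
#' hypergeometric tail on hit counts, treating the foreground regions as
#' a sample from the background regions.  Q-values are Benjamini-Hochberg
#' over all tested terms.
#'
#' @param regions foreground \code{region_set}.
#' @param domains regulatory domains from
#'   \code{\link{build_regulatory_domains}}.
#' @param terms named list of gene-id vectors (\code{\link{read_gmt}}).
#' @param background \code{"whole_genome"} or \code{"region_set"}.
#' @param genome_size total mappable genome size in bp (whole-genome
#'   background).
#' @param background_regions \code{region_set} of background regions
#'   (region-set background).
#' @return data frame with one row per term: \code{term_id},
#'   \code{n_regions_hit}, \code{genome_fraction}, \code{p}, \code{q},
#'   sorted by \code{q} then \code{p}.
#' @export
term_enrichment <- function(regions, domains, terms,
                            background = c("whole_genome", "region_set"),
                            genome_size = NULL, background_regions = NULL) {
  background <- match.arg(background)
  n <- nrow(regions)
  k <- vapply(terms, function(ids)
    sum(region_hits_term(regions, domains, ids)), 0L)
  if (background == "whole_genome") {
    if (is.null(genome_size)) stop("genome_size required")
    cov <- vapply(terms, function(ids) term_coverage(domains, ids), 0)
    if (any(cov == 0))
      stop("term(s) with zero-coverage domains: ",
           paste(names(terms)[cov == 0], collapse = ", "))
    frac <- pmin(1, cov / genome_size)
    p <- stats::pbinom(k - 1, n, frac, lower.tail = FALSE)
  } else {
    if (is.null(background_regions)) stop("background_regions required")
    N <- nrow(background_regions)
    K <- vapply(terms, function(ids)
      sum(region_hits_term(background_regions, domains, ids)), 0L)
    frac <- K / N
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(terms), n_regions_hit = k,
                    genome_fraction = frac, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, out$p, out$term_id), ]
}
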