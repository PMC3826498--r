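#' Construct a region set
#'
#' A \code{region_set} is a sorted data frame of genomic intervals in
#' 0-based half-open (BED) coordinates, carrying a genome label and, per
#' interval, the set of source labels it derives from.
#'
#' @param chrom character vector of chromosome ids.
#' @param start,end integer vectors; 0-based inclusive start, exclusive end.
#' @param name optional region ids; auto-generated when \code{NULL}.
#' @param sources either a single source label recycled to all intervals,
#'   a character vector (one label per interval), or a list of character
#'   vectors.
#' @param genome_id assembly label; all sets entering a joint operation
#'   must agree.
#' @return An object of class \code{region_set}: a data frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{name} and a list column
#'   \code{sources}, sorted by (chrom, start, end).
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), name = NULL, sources = character(0),
                       genome_id = "unspecified") {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  if (n > 0) {
    if (any(is.na(start) | is.na(end)))
      stop("non-integer coordinates")
    if (any(start < 0)) stop("negative start coordinate")
    bad <- which(end <= start)
    if (length(bad))
      stop("end <= start for interval(s) ", paste(head(bad, 5), collapse = ", "))
  }
  if (is.null(name)) name <- if (n) paste0("region_", seq_len(n)) else character()
  if (!is.list(sources)) {
    sources <- as.character(sources)
    if (length(sources) == 1L) sources <- rep(sources, n)
    if (n > 0 && length(sources) != n)
      stop("sources must have length 1 or length(chrom)")
    sources <- as.list(sources)
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), stringsAsFactors = FALSE)
  df$sources <- sources
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome_id = genome_id,
            class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d interval(s) on genome '%s'\n",
              nrow(x), genome_id(x)))
  if (nrow(x)) {
    show <- as.data.frame(head(x, 8))
    show$sources <- vapply(show$sources, paste, "", collapse = ",")
    print(show)
    if (nrow(x) > 8) cat("...\n")
  }
  invisible(x)
}

#' Genome label of a region set
#' @param x a \code{region_set}.
#' @export
genome_id <- function(x) attr(x, "genome_id") %||% "unspecified"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interval lengths of a region set
#' @param x a \code{region_set}.
#' @export
region_widths <- function(x) x$end - x$start

as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_rs <- function(gr, sources, genome_id, name = NULL) {
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             name = name, sources = sources, genome_id = genome_id)
}

#' Read a BED3+ file into a region set
#'
#' Tab- or space-separated; \code{track} and \code{browser} lines and
#' comments are ignored.  Column 4, when present, is taken as the region
#' name.  Malformed lines are rejected with their line number.
#'
#' @param path BED file path.
#' @param source_label label recorded as the provenance of every interval.
#' @param genome_id assembly label.
#' @return a \code{region_set}.
#' @export
read_regions <- function(path, source_label = basename(path),
                         genome_id = "unspecified") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(region_set(genome_id = genome_id))
  fields <- strsplit(trimws(lines[idx]), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(e <= s | s < 0)
  if (length(bad))
    stop("line ", idx[bad[1]], ": invalid interval (end <= start or start < 0)")
  name <- ifelse(nf >= 4, vapply(fields, `[`, "", 4L), NA)
  if (anyNA(name)) name <- NULL
  region_set(chrom, s, e, name = name, sources = source_label,
             genome_id = genome_id)
}

#' Write a region set as BED
#'
#' @param x a \code{region_set}.
#' @param path output path.  Source labels are joined with \code{","} in
#'   column 5-adjacent score slot is omitted; output is BED4.
#' @export
write_regions <- function(x, path) {
  df <- data.frame(x$chrom, x$start, x$end, x$name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge several region sets into a non-redundant set
#'
#' Overlapping or bookended (touching) intervals on the same chromosome
#' are collapsed into one interval spanning their union; the merged
#' interval carries the union of its members' source labels.  The union
#' of covered bases is preserved exactly.
#'
#' @param sets a list of \code{region_set}s (or a single one) sharing a
#'   genome label.
#' @param prefix name prefix for the merged intervals.
#' @return a \code{region_set} with no two intervals on the same
#'   chromosome overlapping or touching.
#' @export
merge_region_sets <- function(sets, prefix = "merged") {
  if (inherits(sets, "region_set")) sets <- list(sets)
  gids <- unique(vapply(sets, genome_id, ""))
  if (length(gids) > 1)
    stop("mixed genome_id: ", paste(gids, collapse = ", "))
  all <- do.call(rbind, lapply(sets, as.data.frame))
  if (is.null(all) || nrow(all) == 0)
    return(region_set(genome_id = if (length(gids)) gids else "unspecified"))
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  src <- lapply(GenomicRanges::mcols(red)$revmap, function(i)
    sort(unique(unlist(all$sources[i]))))
  rs <- granges_to_rs(red, src, gids,
                      name = sprintf("%s_%d", prefix, seq_along(red)))
  rs
}

#' Remove regions overlapping coding exons
#'
#' A region is dropped if it shares at least one base with any coding
#' exon of any transcript (half-open semantics: regions merely abutting
#' an exon are kept).  The number and names of dropped regions are
#' recorded in the \code{"dropped"} attribute.
#'
#' @param regions a \code{region_set}.
#' @param genes a \code{gene_models} object (see
#'   \code{\link{gene_models}}); its exon table must carry an
#'   \code{is_coding} flag.
#' @return the surviving \code{region_set}; \code{attr(,"dropped")} holds
#'   the names of removed regions.
#' @export
filter_coding <- function(regions, genes) {
  if (nrow(regions) == 0) {
    attr(regions, "dropped") <- character()
    return(regions)
  }
  ex <- genes$exons[genes$exons$is_coding, , drop = FALSE]
  if (nrow(ex) == 0) {
    attr(regions, "dropped") <- character()
    return(regions)
  }
  hit <- overlaps_any(regions, ex)
  out <- regions[!hit, , drop = FALSE]
  res <- region_set(out$chrom, out$start, out$end, out$name, out$sources,
                    genome_id = genome_id(regions))
  attr(res, "dropped") <- regions$name[hit]
  res
}

## >=1 bp overlap of regions (region_set/data.frame, 0-based half-open)
## with a 0-based half-open interval table
overlaps_any <- function(regions, tab) {
  if (nrow(tab) == 0) return(rep(FALSE, nrow(regions)))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  gt <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1L, tab$end))
  # disjoint seqlevel sets are routine here (chromosomes without
  # annotations); the seqlevel warning is not informative
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, gt))
  out <- rep(FALSE, nrow(regions))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Classify the genomic context of non-coding regions
#'
#' Assigns exactly one label per region, using a fixed precedence so the
#' categories are disjoint: \code{pseudogene} > \code{lincRNA_exon} >
#' \code{miRNA} > \code{intronic} > \code{intergenic}.  \code{intronic}
#' means the region overlaps the span of a protein-coding gene (having
#' already survived \code{\link{filter_coding}}).
#'
#' @param regions a \code{region_set} with no coding-exon overlap.
#' @param genes a \code{gene_models} object whose gene table carries
#'   \code{gene_type} (\code{protein_coding}, \code{pseudogene},
#'   \code{lincRNA}, \code{miRNA}, ...).
#' @return character vector of context labels, one per region.
#' @export
classify_context <- function(regions, genes) {
  g <- genes$genes
  lab <- rep("intergenic", nrow(regions))
  # precedence applied from lowest to highest so later assignments win
  pc <- g[g$gene_type == "protein_coding", , drop = FALSE]
  lab[overlaps_any(regions, pc)] <- "intronic"
  mir <- g[g$gene_type == "miRNA", , drop = FALSE]
  lab[overlaps_any(regions, mir)] <- "miRNA"
  linc_ex <- merge(genes$exons, g[g$gene_type == "lincRNA", "gene_id",
                                  drop = FALSE], by = "gene_id")
  lab[overlaps_any(regions, linc_ex)] <- "lincRNA_exon"
  ps <- g[grepl("pseudogene", g$gene_type), , drop = FALSE]
  lab[overlaps_any(regions, ps)] <- "pseudogene"
  lab
}

#' Signed distance from region midpoints to the nearest TSS
#'
#' Distance is measured from the region midpoint (integer floor of
#' (start+end)/2) to the nearest transcription start site on the same
#' chromosome.  The sign encodes orientation along the chromosome
#' coordinate axis: negative when the nearest TSS lies at a smaller
#' coordinate than the midpoint (upstream on the axis), positive when it
#' lies beyond it.  A TSS falling inside the region gives distance 0.
#'
#' @param regions a \code{region_set}.
#' @param tss data frame with columns \code{chrom} and \code{pos}
#'   (0-based TSS positions), e.g. from \code{\link{tss_index}}.
#' @return numeric vector of signed distances in bp; \code{NA} for
#'   regions on chromosomes without any TSS.
#' @export
tss_distance <- function(regions, tss) {
  if (nrow(tss) == 0) stop("empty TSS index")
  mid <- (regions$start + regions$end) %/% 2L
  out <- rep(NA_real_, nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    pos <- sort(tss$pos[tss$chrom == chr])
    if (!length(pos)) next
    for (i in ri) {
      d <- pos - mid[i]
      j <- which.min(abs(d))
      inside <- any(pos >= regions$start[i] & pos < regions$end[i])
      out[i] <- if (inside) 0 else d[j]
    }
  }
  out
}

#' Mann-Whitney U test (midrank ties)
#'
#' Rank-sum U with midranks for ties.  The two-sided p-value is computed
#' by exact enumeration when feasible (all label assignments when ties
#' are present, the exact null distribution otherwise) and by a normal
#' approximation with tie-corrected variance for larger samples
#' (\code{n1 * n2 > 400}).
#'
#' @param a,b numeric samples.
#' @return a list with \code{U} (the statistic for sample \code{a}),
#'   \code{p_two_sided}, \code{n1}, \code{n2} and the \code{method} used.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact_ok <- n1 * n2 <= 400
  if (exact_ok && !ties) {
    # exact null distribution of U (no ties)
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(1, p)
    method <- "exact"
  } else if (exact_ok && ties && choose(n1 + n2, n1) <= 2e5) {
    # full enumeration of label assignments under ties
    v <- c(a, b)
    rr <- rank(v)
    combs <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(rr[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tab <- table(c(a, b))
    tiecor <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tiecor)
    if (sigma2 <= 0) return(list(U = U, p_two_sided = 1, n1 = n1, n2 = n2,
                                 method = "normal"))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p_two_sided = p, n1 = n1, n2 = n2, method = method)
}

#' Summary statistics of a compiled region set
#'
#' @param regions a \code{region_set}.
#' @param genes optional \code{gene_models}; enables context fractions.
#' @param tss optional TSS index; enables TSS-distance moments.
#' @return a list with \code{n}, \code{mean_length}, \code{sd_length},
#'   and (when inputs allow) \code{mean_abs_tss_distance},
#'   \code{sd_abs_tss_distance} and \code{context_fractions} (summing
#'   to 1).  Moments are \code{NA} for empty sets.
#' @export
summarize_regions <- function(regions, genes = NULL, tss = NULL) {
  n <- nrow(regions)
  w <- region_widths(regions)
  out <- list(n = n,
              mean_length = if (n) mean(w) else NA_real_,
              sd_length = if (n > 1) stats::sd(w) else if (n == 1) 0 else NA_real_)
  if (!is.null(tss) && n) {
    d <- abs(tss_distance(regions, tss))
    out$mean_abs_tss_distance <- mean(d, na.rm = TRUE)
    out$sd_abs_tss_distance <- if (n > 1) stats::sd(d, na.rm = TRUE) else 0
  }
  if (!is.null(genes) && n) {
    ctx <- classify_context(regions, genes)
    lv <- c("pseudogene", "lincRNA_exon", "miRNA", "intronic", "intergenic")
    out$context_fractions <- table(factor(ctx, levels = lv)) / n
  }
  out
}
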