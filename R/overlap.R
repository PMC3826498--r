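#' Read a peak-set manifest
#'
#' Manifest TSV with header columns \code{path}, \code{mark},
#' \code{context}; each path is a BED3+ file of peaks for one mark in one
#' cellular context.  Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file.
#' @param genome_id assembly label for the loaded peak sets.
#' @return list of peak sets, each a list with \code{mark},
#'   \code{context}, \code{intervals} (a \code{region_set}).
#' @export
read_peak_manifest <- function(path, genome_id = "unspecified") {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("path", "mark", "context") %in% names(man)))
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(dirname(path), p)
    peak_set(read_regions(p, source_label = man$mark[i],
                          genome_id = genome_id),
             mark = man$mark[i], context = man$context[i])
  })
}

#' Construct a peak set
#' @param intervals a \code{region_set} of peaks.
#' @param mark mark label (e.g. \code{H3K4me1}, \code{H3K27ac},
#'   \code{P300}).
#' @param context cell-line / cellular-context label.
#' @export
peak_set <- function(intervals, mark, context) {
  stopifnot(inherits(intervals, "region_set"))
  structure(list(mark = mark, context = context, intervals = intervals),
            class = "peak_set")
}

#' Overlap regions with peak sets
#'
#' A region hits a (mark, context) peak set when it shares at least
#' \code{min_frac} of its length (default: any single base) with a peak.
#'
#' @param regions a \code{region_set}.
#' @param peaksets list of \code{peak_set} objects.
#' @param min_frac minimum overlap as a fraction of the region length;
#'   0 means >= 1 bp.
#' @return an \code{evidence_matrix}: logical matrix regions x peak sets,
#'   with column metadata in attributes \code{marks} and \code{contexts}.
#' @export
overlap_peaks <- function(regions, peaksets, min_frac = 0) {
  gid <- unique(c(genome_id(regions),
                  vapply(peaksets, function(p) genome_id(p$intervals), "")))
  if (length(gid) > 1)
    stop("genome mismatch: ", paste(gid, collapse = ", "))
  hits <- vapply(peaksets, function(p) {
    if (min_frac <= 0) return(overlaps_any(regions, p$intervals))
    ovl <- overlap_bases(regions, p$intervals)
    ovl >= pmax(1, min_frac * region_widths(regions))
  }, logical(nrow(regions)))
  hits <- matrix(hits, nrow = nrow(regions))
  colnames(hits) <- vapply(peaksets, function(p)
    paste(p$mark, p$context, sep = "."), "")
  rownames(hits) <- regions$name
  structure(hits,
            marks = vapply(peaksets, function(p) p$mark, ""),
            contexts = vapply(peaksets, function(p) p$context, ""),
            class = c("evidence_matrix", "matrix"))
}

## per-region count of bases overlapped by a peak table (union of peaks)
overlap_bases <- function(regions, peaks) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  gp <- GenomicRanges::reduce(
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$start + 1L, peaks$end)))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, gp))
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr)[S4Vectors::queryHits(ov)],
    GenomicRanges::ranges(gp)[S4Vectors::subjectHits(ov)]))
  out <- numeric(nrow(regions))
  if (length(ov)) {
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Collapse an evidence matrix over contexts
#'
#' @param ev an \code{evidence_matrix}.
#' @return logical matrix regions x marks: hit in at least one context.
#' @export
collapse_by_mark <- function(ev) {
  marks <- attr(ev, "marks")
  out <- vapply(unique(marks), function(m)
    apply(ev[, marks == m, drop = FALSE], 1, any), logical(nrow(ev)))
  matrix(out, nrow = nrow(ev),
         dimnames = list(rownames(ev), unique(marks)))
}

#' Read a genome-segmentation track
#'
#' BED file whose name column carries the state label.  Segments within a
#' track must not overlap.
#'
#' @param path BED file.
#' @param context cell-line label.
#' @param genome_id assembly label.
#' @return a list with \code{context} and \code{segments} (data frame
#'   with \code{chrom}, \code{start}, \code{end}, \code{state}).
#' @export
read_segmentation <- function(path, context, genome_id = "unspecified") {
  rs <- read_regions(path, source_label = context, genome_id = genome_id)
  seg <- data.frame(chrom = rs$chrom, start = rs$start, end = rs$end,
                    state = rs$name, stringsAsFactors = FALSE)
  segmentation_track(seg, context)
}

#' Construct a segmentation track
#' @param segments data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{state}.
#' @param context cell-line label.
#' @export
segmentation_track <- function(segments, context) {
  o <- order(segments$chrom, segments$start)
  segments <- segments[o, , drop = FALSE]
  by_chr <- split(segments, segments$chrom)
  for (s in by_chr)
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments within track '", context, "'")
  structure(list(context = context, segments = segments),
            class = "segmentation_track")
}

#' Assign a segmentation state to each region
#'
#' The state of the segment containing the region midpoint; when the
#' region straddles several segments, the state covering the largest part
#' of the region wins, ties going to the leftmost such segment.  Regions
#' whose midpoint falls in an annotation gap and that overlap no segment
#' are \code{"unannotated"}.
#'
#' @param regions a \code{region_set}.
#' @param tracks list of \code{segmentation_track}s (or a single one).
#' @return character matrix regions x contexts of state labels.
#' @export
assign_states <- function(regions, tracks) {
  if (inherits(tracks, "segmentation_track")) tracks <- list(tracks)
  out <- vapply(tracks, function(tr) {
    seg <- tr$segments
    vapply(seq_len(nrow(regions)), function(i) {
      same <- seg[seg$chrom == regions$chrom[i], , drop = FALSE]
      if (!nrow(same)) return("unannotated")
      ov <- pmin(same$end, regions$end[i]) - pmax(same$start, regions$start[i])
      ok <- ov > 0
      if (!any(ok)) return("unannotated")
      tot <- tapply(ov[ok], same$state[ok], sum)  # per-state base counts
      best <- names(tot)[tot == max(tot)]
      if (length(best) == 1) return(best)
      cand <- which(ok & same$state %in% best)
      same$state[cand[1]]  # tie: segments sorted, first = leftmost
    }, "")
  }, character(nrow(regions)))
  out <- matrix(out, nrow = nrow(regions))
  dimnames(out) <- list(regions$name,
                        vapply(tracks, function(t) t$context, ""))
  out
}

#' Summarize enhancer evidence
#'
#' @param ev an \code{evidence_matrix} from \code{\link{overlap_peaks}}.
#' @param states optional state matrix from \code{\link{assign_states}}.
#' @return list with \code{per_mark} (regions hit per mark, any context),
#'   \code{any_evidence} (regions hit by >= 1 mark) and, when states are
#'   given, \code{per_state} (regions in each state in >= 1 context).
#' @export
summarize_evidence <- function(ev, states = NULL) {
  bym <- collapse_by_mark(ev)
  out <- list(per_mark = colSums(bym),
              any_evidence = sum(apply(bym, 1, any)))
  if (!is.null(states)) {
    lv <- sort(unique(as.vector(states)))
    out$per_state <- vapply(lv, function(s)
      sum(apply(states == s, 1, any)), 0L)
  }
  out
}
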