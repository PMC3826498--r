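#' Construct a position weight matrix
#'
#' Counts or probabilities are normalized per position after adding a
#' pseudocount; scanning scores are log2 odds against the background.
#'
#' @param matrix numeric matrix, width x 4, columns A, C, G, T (counts or
#'   probabilities).
#' @param tf_id identifier.
#' @param name display name; defaults to \code{tf_id}.
#' @param pseudocount added to every cell before normalization.
#' @param background base frequencies (A, C, G, T); default uniform.
#' @return an object of class \code{pwm}.
#' @export
pwm <- function(matrix, tf_id, name = tf_id, pseudocount = 0.01,
                background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 1) stop("PWM width must be >= 1")
  if (any(matrix < 0)) stop("negative PWM entries")
  m <- matrix + pseudocount
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  bg <- background / sum(background)
  structure(list(tf_id = tf_id, name = name, prob = m,
                 logodds = log2(sweep(m, 2, bg, "/")),
                 pseudocount = pseudocount, background = bg,
                 width = nrow(m)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%s), width %d, max score %.2f bits\n",
              x$tf_id, x$name, x$width, sum(apply(x$logodds, 1, max))))
  invisible(x)
}

#' Maximum achievable log-odds score of a PWM
#' @param x a \code{pwm}.
#' @export
max_score <- function(x) sum(apply(x$logodds, 1, max))

#' Read TRANSFAC-format matrices
#'
#' Minimal TRANSFAC matrix parser: records delimited by \code{//}, id
#' from the \code{ID} (fallback \code{AC}) line, name from \code{NA},
#' count rows introduced by two-digit position lines under a \code{P0}
#' (or \code{PO}) header.
#'
#' @param path file path.
#' @param ... passed to \code{\link{pwm}} (pseudocount, background).
#' @return list of \code{pwm} objects.
#' @export
read_transfac <- function(path, ...) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (rec in recs) {
    idl <- grep("^ID\\s+", rec, value = TRUE)
    if (!length(idl)) idl <- grep("^AC\\s+", rec, value = TRUE)
    if (!length(idl)) next
    id <- sub("^..\\s+", "", idl[1])
    nal <- grep("^NA\\s+", rec, value = TRUE)
    nm <- if (length(nal)) sub("^NA\\s+", "", nal[1]) else id
    rows <- grep("^[0-9][0-9]\\s+", rec, value = TRUE)
    if (!length(rows)) next
    mat <- do.call(rbind, lapply(rows, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:5])
    }))
    out[[id]] <- pwm(mat, tf_id = id, name = nm, ...)
  }
  out
}

#' Write matrices in TRANSFAC format
#' @param pwms list of \code{pwm} objects.
#' @param path output path.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(sprintf("ID %s", p$tf_id), sprintf("NA %s", p$name),
                 "P0        A        C        G        T"), con)
    m <- p$prob * 100   # conventional count scale
    for (i in seq_len(p$width))
      writeLines(sprintf("%02d %8.3f %8.3f %8.3f %8.3f", i,
                         m[i, 1], m[i, 2], m[i, 3], m[i, 4]), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read MEME minimal-format motifs
#'
#' @param path MEME minimal format file.
#' @param ... passed to \code{\link{pwm}}.
#' @return list of \code{pwm} objects.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1]][1]
    hdr <- grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1] + s
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    out[[id]] <- pwm(mat, tf_id = id, ...)
  }
  out
}

seq_to_int <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  x  # N and other ambiguity codes become NA
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## log-odds score at every offset of an integer-coded sequence;
## windows containing N (NA codes) score NA
scan_scores <- function(si, lo) {
  w <- nrow(lo)
  n <- length(si) - w + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  nas <- logical(n)
  for (j in seq_len(w)) {
    idx <- si[j:(j + n - 1)]
    bad <- is.na(idx)
    nas <- nas | bad
    idx[bad] <- 1L
    sc <- sc + lo[j, idx]
  }
  sc[nas] <- NA
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset with log2(P_pwm / P_background); a hit is any
#' window scoring at least \code{threshold_frac} of the maximum
#' achievable score.  Windows containing N are skipped.  Reverse-strand
#' hits are reported at the forward-coordinate offset of the window
#' start.
#'
#' @param seq character DNA sequence (A/C/G/T/N).
#' @param pwm a \code{pwm} object.
#' @param threshold_frac hit threshold as a fraction of
#'   \code{\link{max_score}}; default 0.8.
#' @return data frame with \code{position} (0-based), \code{strand},
#'   \code{score}, sorted by position.
#' @export
scan_pwm <- function(seq, pwm, threshold_frac = 0.8) {
  if (nchar(seq) < pwm$width)
    stop("sequence shorter than motif width")
  thr <- threshold_frac * max_score(pwm)
  si <- seq_to_int(seq)
  fwd <- scan_scores(si, pwm$logodds)
  # reverse strand: scan the reverse complement, map offsets back
  ri <- seq_to_int(revcomp_chr(seq))
  rev <- scan_scores(ri, pwm$logodds)
  n <- length(fwd)
  hits_f <- which(!is.na(fwd) & fwd >= thr)
  hits_r <- which(!is.na(rev) & rev >= thr)
  out <- data.frame(
    position = c(hits_f - 1L, n - hits_r),  # 0-based forward offsets
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    score = c(fwd[hits_f], rev[hits_r]))
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Count PWM hits in a sequence
#' @param seq character DNA sequence.
#' @param pwm a \code{pwm}.
#' @param threshold_frac hit threshold fraction.
#' @export
count_hits <- function(seq, pwm, threshold_frac = 0.8) {
  if (nchar(seq) < pwm$width) return(0L)
  nrow(scan_pwm(seq, pwm, threshold_frac))
}

#' Construct a human/chimp ortholog sequence pair
#'
#' @param region_id identifier.
#' @param human_seq,chimp_seq equal-length DNA strings (ungapped
#'   comparison); substitution positions are derived as the mismatch
#'   positions unless supplied.
#' @param substitutions optional 0-based positions of substitutions.
#' @export
ortholog_pair <- function(region_id, human_seq, chimp_seq,
                          substitutions = NULL) {
  human_seq <- toupper(human_seq); chimp_seq <- toupper(chimp_seq)
  if (nchar(human_seq) != nchar(chimp_seq))
    stop("ortholog sequences must be pre-aligned to equal length")
  if (is.null(substitutions)) {
    h <- strsplit(human_seq, "")[[1]]
    c0 <- strsplit(chimp_seq, "")[[1]]
    substitutions <- which(h != c0) - 1L
  }
  structure(list(region_id = region_id, human_seq = human_seq,
                 chimp_seq = chimp_seq,
                 substitutions = as.integer(substitutions)),
            class = "ortholog_pair")
}

#' Read ortholog pairs from paired FASTA files
#'
#' Sequences are matched by record id across the two files.
#'
#' @param human_fa,chimp_fa FASTA paths.
#' @return list of \code{ortholog_pair}s.
#' @export
read_ortholog_pairs <- function(human_fa, chimp_fa) {
  h <- Biostrings::readDNAStringSet(human_fa)
  c0 <- Biostrings::readDNAStringSet(chimp_fa)
  ids <- intersect(names(h), names(c0))
  lapply(ids, function(id)
    ortholog_pair(id, as.character(h[[id]]), as.character(c0[[id]])))
}

#' Per-TF binding-site count divergence of an ortholog pair
#'
#' @param pair an \code{ortholog_pair}.
#' @param pwms list of \code{pwm} objects.
#' @param threshold_frac hit threshold fraction.
#' @return data frame with one row per TF: \code{region_id},
#'   \code{tf_id}, \code{n_human}, \code{n_chimp},
#'   \code{delta = n_human - n_chimp}.
#' @export
count_divergence <- function(pair, pwms, threshold_frac = 0.8) {
  nh <- vapply(pwms, function(p)
    count_hits(pair$human_seq, p, threshold_frac), 0L)
  nc <- vapply(pwms, function(p)
    count_hits(pair$chimp_seq, p, threshold_frac), 0L)
  data.frame(region_id = pair$region_id,
             tf_id = vapply(pwms, function(p) p$tf_id, ""),
             n_human = nh, n_chimp = nc, delta = nh - nc,
             stringsAsFactors = FALSE, row.names = NULL)
}

## both-strand hit count on an integer-coded sequence; the reverse
## complement of codes (A=1..T=4) is rev(5 - si), NA (N) preserved
count_hits_int <- function(si, lo, thr) {
  f <- scan_scores(si, lo)
  r <- scan_scores(rev(5L - si), lo)
  sum(f >= thr, na.rm = TRUE) + sum(r >= thr, na.rm = TRUE)
}

#' Permutation significance of binding-site count divergence
#'
#' Null model: the observed substitutions (count and substituted-to
#' bases) are re-scattered uniformly without replacement over the
#' positions of the chimpanzee sequence, and the hit-count difference is
#' recomputed.  The two-sided p-value uses the add-one estimator
#' \code{(1 + #(|delta_null| >= |delta_obs|)) / (n_perm + 1)}, so p is
#' never 0.  Pairs with zero substitutions return p = 1.
#'
#' @param pair an \code{ortholog_pair}.
#' @param pwm a \code{pwm}.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed (local to this call).
#' @param threshold_frac hit threshold fraction.
#' @param detail when \code{TRUE}, return a list with the p-value, the
#'   observed delta and the vector of null deltas (e.g. for calibration
#'   studies with randomized tie-breaking); default returns the p-value
#'   alone.
#' @return the permutation p-value (or a detail list).
#' @export
divergence_significance <- function(pair, pwm, n_perm = 999, seed = 1,
                                    threshold_frac = 0.8,
                                    detail = FALSE) {
  subs <- pair$substitutions
  if (!length(subs))
    return(if (detail) list(p = 1, d_obs = 0L, d_null = integer()) else 1)
  thr <- threshold_frac * max_score(pwm)
  lo <- pwm$logodds
  ci <- seq_to_int(pair$chimp_seq)
  hi <- seq_to_int(pair$human_seq)
  to_int <- hi[subs + 1L]
  n_chimp <- count_hits_int(ci, lo, thr)
  d_obs <- count_hits_int(hi, lo, thr) - n_chimp
  L <- length(ci)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  m <- length(subs)
  d_null <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pos <- sample.int(L, m)
    null_si <- ci
    null_si[pos] <- if (m > 1) sample(to_int) else to_int
    d_null[b] <- count_hits_int(null_si, lo, thr) - n_chimp
  }
  p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_perm + 1)
  if (detail) list(p = p, d_obs = d_obs, d_null = d_null) else p
}

#' TFBS divergence over a cohort of ortholog pairs
#'
#' Runs \code{\link{count_divergence}} for every pair and, for TFs with a
#' non-zero hit-count difference (|delta| of zero always yields p = 1
#' under the two-sided permutation null, which is therefore skipped),
#' \code{\link{divergence_significance}}.
#'
#' @param pairs list of \code{ortholog_pair}s.
#' @param pwms list of \code{pwm}s.
#' @param n_perm permutations per test.
#' @param seed root seed; each (pair, TF) test gets a derived seed.
#' @param threshold_frac hit threshold fraction.
#' @return data frame of per-(region, TF) results with \code{p_perm}.
#' @export
tfbs_divergence <- function(pairs, pwms, n_perm = 999, seed = 1,
                            threshold_frac = 0.8) {
  res <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    r <- count_divergence(pairs[[i]], pwms, threshold_frac)
    r$p_perm <- 1
    for (j in which(r$delta != 0)) {
      r$p_perm[j] <- divergence_significance(
        pairs[[i]], pwms[[j]], n_perm = n_perm,
        seed = seed + 13L * i + j, threshold_frac = threshold_frac)
    }
    r
  }))
  rownames(res) <- NULL
  res
}

#' Cohort summary of TFBS divergence
#'
#' @param results output of \code{\link{tfbs_divergence}}.
#' @param alpha per-TF significance level (uncorrected), default 0.1.
#' @return list with \code{per_region} (significant-TF count per region),
#'   \code{mean_sig_tfs} and \code{frac_regions_sig} (fraction of regions
#'   with at least one significant TF).
#' @export
summarize_divergence <- function(results, alpha = 0.1) {
  sig <- results$p_perm < alpha
  per <- tapply(sig, results$region_id, sum)
  per <- setNames(as.vector(per), names(per))
  list(per_region = per,
       mean_sig_tfs = mean(per),
       frac_regions_sig = mean(per >= 1))
}
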