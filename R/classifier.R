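#' Fixed-width windows centred on regions
#'
#' Windows are centred on the region midpoint; odd remainders give the
#' left flank the shorter half.  Windows are clipped at chromosome
#' boundaries and flagged.
#'
#' @param regions a \code{region_set}.
#' @param width window width in bp, default 1500.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return data frame: \code{name}, \code{chrom}, \code{start},
#'   \code{end}, \code{clipped}.
#' @export
extract_window <- function(regions, width = 1500, chrom_lengths) {
  unknown <- setdiff(unique(regions$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("region on unknown chromosome: ", paste(unknown, collapse = ", "))
  mid <- (regions$start + regions$end) %/% 2L
  half_l <- width %/% 2L            # floor: left flank gets the shorter half
  s <- mid - half_l
  e <- s + width
  cl <- as.integer(chrom_lengths[regions$chrom])
  s2 <- pmax(0L, s)
  e2 <- pmin(e, cl)
  data.frame(name = regions$name, chrom = regions$chrom,
             start = as.integer(s2), end = as.integer(e2),
             clipped = s2 != s | e2 != e, stringsAsFactors = FALSE)
}

#' Extract window sequences from a genome
#'
#' @param genome a named \code{DNAStringSet} (one entry per chromosome)
#'   or path to a FASTA file.
#' @param windows data frame from \code{\link{extract_window}}.
#' @return named character vector of sequences.
#' @export
window_seqs <- function(genome, windows) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  out <- vapply(seq_len(nrow(windows)), function(i) {
    as.character(Biostrings::subseq(genome[[windows$chrom[i]]],
                                    windows$start[i] + 1L, windows$end[i]))
  }, "")
  names(out) <- windows$name
  out
}

canonical_kmers <- function(k) {
  kmers <- Biostrings::DNAStringSet(
    do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k))[
      , k:1, drop = FALSE]))
  km <- as.character(kmers)
  rc <- as.character(Biostrings::reverseComplement(kmers))
  canon <- pmin(km, rc)
  list(kmers = km, canon = canon, levels = sort(unique(canon)))
}

#' Reverse-complement-collapsed k-mer spectrum
#'
#' Counts every k-mer window (windows containing N contribute nothing),
#' pools each k-mer with its reverse complement under the
#' lexicographically smaller of the two, and normalizes each sequence's
#' counts to frequencies.
#'
#' @param seqs character vector of DNA sequences (or DNAStringSet).
#' @param k k-mer size, default 5.
#' @return matrix sequences x canonical k-mers of frequencies; rows of
#'   all-N sequences are zero.
#' @export
kmer_features <- function(seqs, k = 5) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  ck <- canonical_kmers(k)
  out <- matrix(0, nrow = nrow(counts), ncol = length(ck$levels),
                dimnames = list(names(seqs), ck$levels))
  for (j in seq_along(ck$kmers))
    out[, ck$canon[j]] <- out[, ck$canon[j]] + counts[, ck$kmers[j]]
  tot <- rowSums(out)
  out[tot > 0, ] <- out[tot > 0, , drop = FALSE] / tot[tot > 0]
  out
}

#' Assemble feature blocks for classification
#'
#' @param seqs character vector of window sequences.
#' @param marks optional logical/numeric matrix of functional-genomics
#'   evidence (rows matching \code{seqs}); coerced to 0/1 doubles.
#' @param conservation optional list of per-base conservation score
#'   vectors (one per sequence); summarized as mean and max, 0 when
#'   absent.
#' @param k k-mer size for the sequence spectrum.
#' @return named list of numeric matrices (feature blocks):
#'   \code{kmer_spectrum} and, when given, \code{marks},
#'   \code{conservation}.
#' @export
featurize <- function(seqs, marks = NULL, conservation = NULL, k = 5) {
  if (!length(seqs)) stop("no sequences")
  blocks <- list(kmer_spectrum = kmer_features(seqs, k = k))
  if (!is.null(marks)) {
    m <- matrix(as.numeric(marks), nrow = length(seqs))
    colnames(m) <- colnames(marks)
    blocks$marks <- m
  }
  if (!is.null(conservation)) {
    cs <- t(vapply(conservation, function(v) {
      if (is.null(v) || !length(v)) c(0, 0) else c(mean(v), max(v))
    }, c(0, 0)))
    colnames(cs) <- c("cons_mean", "cons_max")
    blocks$conservation <- cs
  }
  blocks
}

block_trace_norm <- function(X) {
  tn <- sum(X^2) / nrow(X)      # trace(X X^T) / n
  if (tn <= 0) 1 else tn
}

#' Combine feature blocks into a multi-kernel Gram matrix
#'
#' Each block contributes a linear kernel normalized by its trace/n, and
#' the combined kernel is their weighted sum, which is symmetric positive
#' semidefinite whenever the weights are non-negative.
#'
#' @param blocks named list of feature matrices sharing row count.
#' @param weights named non-negative weights; default equal.  At least
#'   one must be positive.
#' @param blocks2 optional second list of blocks (same names) to obtain
#'   the cross-kernel K(blocks2, blocks); trace normalization always
#'   comes from \code{blocks} (the training side).
#' @return numeric kernel matrix.
#' @export
combine_kernels <- function(blocks, weights = NULL, blocks2 = NULL) {
  nms <- names(blocks)
  if (is.null(weights)) weights <- setNames(rep(1 / length(nms),
                                                length(nms)), nms)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative with at least one positive")
  if (!is.null(blocks2) && !identical(sort(names(blocks2)), sort(nms)))
    stop("mismatched feature blocks")
  n2 <- if (is.null(blocks2)) nrow(blocks[[1]]) else nrow(blocks2[[1]])
  K <- matrix(0, n2, nrow(blocks[[1]]))
  for (b in nms) {
    tn <- block_trace_norm(blocks[[b]])
    Xl <- if (is.null(blocks2)) blocks[[b]] else blocks2[[b]]
    K <- K + weights[[b]] * tcrossprod(Xl, blocks[[b]]) / tn
  }
  if (is.null(blocks2)) K <- (K + t(K)) / 2
  K
}

#' Tissues with stage-2 classifiers
#'
#' The developmental tissues for which tissue-specificity classifiers
#' are trained.
#' @export
TISSUES <- c("brain", "heart", "limb", "neural_tube")

#' Two-stage multi-kernel SVM enhancer predictor
#'
#' Stage 1 is a soft-margin SVM on the combined kernel separating
#' developmental enhancers from genomic background; stage 2 fits a
#' one-vs-rest SVM per tissue (brain, heart, limb, neural tube) on the
#' labelled positives only.  Kernels are linear per feature block,
#' trace-normalized, with configurable non-negative weights (equal by
#' default).
#'
#' @param x named list of feature-block matrices
#'   (\code{\link{featurize}}); all blocks share rows (training
#'   elements).
#' @param y enhancer labels: logical, or factor/character with values
#'   \code{"positive"}/\code{"negative"}.
#' @param tissues optional list (one element per row) of tissue-label
#'   character vectors; only positives may carry tissues.  Tissues with
#'   fewer than \code{min_tissue_pos} positive examples are not trained.
#' @param weights kernel weights, see \code{\link{combine_kernels}}.
#' @param C soft-margin cost, default 1.
#' @param seed RNG seed recorded in the model and used around fitting.
#' @param min_tissue_pos minimum positives per trained tissue, default 5.
#' @return an object of class \code{enhancer_finder} with
#'   \code{predict}, \code{print}, \code{summary} and \code{plot}
#'   methods.
#' @export
enhancer_finder <- function(x, y, tissues = NULL, weights = NULL, C = 1,
                            seed = 1, min_tissue_pos = 5) {
  y <- normalize_labels(y)
  if (length(unique(y)) < 2) stop("both classes required for stage 1")
  nms <- names(x)
  if (is.null(weights))
    weights <- setNames(rep(1 / length(nms), length(nms)), nms)
  # centre each block on its training means: k-mer frequency vectors
  # share a large constant component that would otherwise dominate the
  # linear Gram matrix
  centers <- lapply(x, colMeans)
  x <- mapply(function(X, mu) sweep(X, 2, mu), x, centers,
              SIMPLIFY = FALSE)
  K <- combine_kernels(x, weights)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  s1 <- fit_kernel_svm(K, y == "positive", C)
  stage2 <- list()
  if (!is.null(tissues)) {
    pos <- which(y == "positive")
    if (any(lengths(tissues[y == "negative"]) > 0))
      stop("tissue labels present on negatives")
    for (tis in TISSUES) {
      lab <- vapply(tissues[pos], function(t) tis %in% t, TRUE)
      if (sum(lab) >= min_tissue_pos && sum(!lab) >= 1) {
        Kp <- K[pos, pos, drop = FALSE]
        stage2[[tis]] <- c(fit_kernel_svm(Kp, lab, C), list(rows = pos))
      }
    }
  }
  structure(list(blocks = x, centers = centers, weights = weights,
                 C = C, seed = seed, stage1 = s1, stage2 = stage2,
                 n = length(y), y = y),
            class = "enhancer_finder")
}

normalize_labels <- function(y) {
  if (is.logical(y)) return(ifelse(y, "positive", "negative"))
  y <- as.character(y)
  if (!all(y %in% c("positive", "negative")))
    stop("labels must be 'positive'/'negative' (or logical)")
  y
}

## soft-margin C-SVC on a precomputed kernel; classes are weighted
## inversely to their frequencies so the zero decision threshold is not
## biased by imbalance; decision sign calibrated so positives score high
fit_kernel_svm <- function(K, is_pos, C) {
  y <- factor(ifelse(is_pos, "positive", "negative"),
              levels = c("negative", "positive"))
  cw <- length(y) / (2 * table(y))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = C, class.weights = setNames(as.numeric(cw),
                                                       names(cw)))
  sv <- kernlab::SVindex(fit)
  d <- kernlab::predict(fit,
                        kernlab::as.kernelMatrix(K[, sv, drop = FALSE]),
                        type = "decision")[, 1]
  sgn <- if (mean(d[is_pos]) >= mean(d[!is_pos])) 1 else -1
  list(fit = fit, sv = sv, sign = sgn)
}

svm_decision <- function(model, Kcross) {
  d <- kernlab::predict(
    model$fit,
    kernlab::as.kernelMatrix(Kcross[, model$sv, drop = FALSE]),
    type = "decision")[, 1]
  model$sign * d
}

#' @export
print.enhancer_finder <- function(x, ...) {
  cat("Two-stage multi-kernel SVM enhancer predictor\n")
  cat(sprintf("  training elements: %d (%d positive)\n", x$n,
              sum(x$y == "positive")))
  cat(sprintf("  feature blocks: %s\n",
              paste(sprintf("%s (w=%.2g)", names(x$weights), x$weights),
                    collapse = ", ")))
  cat(sprintf("  C = %g, seed = %d\n", x$C, as.integer(x$seed)))
  if (length(x$stage2))
    cat(sprintf("  tissue classifiers: %s\n",
                paste(names(x$stage2), collapse = ", ")))
  invisible(x)
}

#' @export
summary.enhancer_finder <- function(object, ...) {
  K <- combine_kernels(object$blocks, object$weights)
  d <- svm_decision(object$stage1, K)
  acc <- mean((d > 0) == (object$y == "positive"))
  out <- list(n = object$n, n_positive = sum(object$y == "positive"),
              training_accuracy = acc,
              tissues_trained = names(object$stage2),
              weights = object$weights, C = object$C)
  class(out) <- "summary.enhancer_finder"
  out
}

#' @export
print.summary.enhancer_finder <- function(x, ...) {
  cat(sprintf("enhancer_finder: %d elements (%d positive)\n",
              x$n, x$n_positive))
  cat(sprintf("  training accuracy (stage 1): %.3f\n",
              x$training_accuracy))
  if (length(x$tissues_trained))
    cat(sprintf("  stage-2 tissues: %s\n",
                paste(x$tissues_trained, collapse = ", ")))
  invisible(x)
}

#' Predict enhancer activity and tissues for new elements
#'
#' @param object an \code{enhancer_finder} model.
#' @param newdata named list of feature blocks matching the training
#'   blocks.
#' @param tissue_threshold stage-2 decision value above which a tissue is
#'   assigned, default 0 ("no confident tissue" when none exceeds it).
#' @param ... unused.
#' @return data frame: \code{score1}, \code{is_enhancer}, one
#'   \code{score_<tissue>} column per trained tissue, and
#'   \code{tissues_assigned} (comma-joined, empty when no confident
#'   assignment; always empty on stage-1 negatives).
#' @export
predict.enhancer_finder <- function(object, newdata, tissue_threshold = 0,
                                    ...) {
  newdata <- newdata[names(object$blocks)]
  newdata <- mapply(function(X, mu) sweep(X, 2, mu), newdata,
                    object$centers[names(object$blocks)],
                    SIMPLIFY = FALSE)
  Kc <- combine_kernels(object$blocks, object$weights, blocks2 = newdata)
  score1 <- svm_decision(object$stage1, Kc)
  out <- data.frame(score1 = score1, is_enhancer = score1 > 0)
  assigned <- rep("", nrow(out))
  for (tis in names(object$stage2)) {
    m <- object$stage2[[tis]]
    sc <- svm_decision(m, Kc[, m$rows, drop = FALSE])
    out[[paste0("score_", tis)]] <- sc
    assigned <- ifelse(out$is_enhancer & sc > tissue_threshold,
                       ifelse(nzchar(assigned),
                              paste(assigned, tis, sep = ","), tis),
                       assigned)
  }
  out$tissues_assigned <- assigned
  rownames(out) <- rownames(newdata[[1]])
  out
}

#' Stage-1 decision values by class
#'
#' @param x an \code{enhancer_finder} model.
#' @param ... passed to \code{boxplot}.
#' @export
plot.enhancer_finder <- function(x, ...) {
  K <- combine_kernels(x$blocks, x$weights)
  d <- svm_decision(x$stage1, K)
  graphics::boxplot(d ~ factor(x$y), xlab = "training label",
                    ylab = "stage-1 decision value", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or positive/negative) labels.
#' @export
auc_score <- function(scores, labels) {
  if (!is.logical(labels)) labels <- normalize_labels(labels) == "positive"
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated stage-1 AUC
#'
#' @param x named list of feature blocks.
#' @param y enhancer labels.
#' @param folds number of folds, default 5.
#' @param seed fold-assignment seed.
#' @param ... passed to \code{\link{enhancer_finder}}.
#' @return the pooled AUC over held-out decision values.
#' @export
cv_auc <- function(x, y, folds = 5, seed = 1, ...) {
  y <- normalize_labels(y)
  n <- length(y)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    xtr <- lapply(x, function(X) X[tr, , drop = FALSE])
    xte <- lapply(x, function(X) X[!tr, , drop = FALSE])
    fit <- enhancer_finder(xtr, y[tr], seed = seed, ...)
    scores[!tr] <- predict(fit, xte)$score1
  }
  auc_score(scores, y == "positive")
}

#' Genome-wide background prediction rate
#'
#' Samples windows uniformly from the genome (optionally avoiding a set
#' of excluded regions, e.g. coding exons), featurizes them with the
#' model's k-mer block (marks and conservation blocks, when the model
#' has them, default to zero for background windows unless supplied),
#' and returns the fraction predicted positive.
#'
#' @param model an \code{enhancer_finder}.
#' @param genome named \code{DNAStringSet} or FASTA path.
#' @param n_windows number of windows to sample (> 0).
#' @param width window width; defaults to the typical training width of
#'   1500.
#' @param seed sampling seed.
#' @param exclude optional \code{region_set} of intervals whose windows
#'   are rejected.
#' @param k k-mer size used at training.
#' @return fraction of sampled windows predicted positive.
#' @export
background_rate <- function(model, genome, n_windows, width = 1500,
                            seed = 1, exclude = NULL, k = 5) {
  if (n_windows <= 0) stop("n_windows must be positive")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  lens <- vapply(genome, length, 0L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  seqs <- character(0)
  while (length(seqs) < n_windows) {
    chr <- sample(names(lens), 1, prob = lens)
    if (lens[chr] < width) next
    s <- sample.int(lens[chr] - width + 1L, 1)
    if (!is.null(exclude)) {
      w <- data.frame(chrom = chr, start = s - 1L, end = s - 1L + width)
      if (overlaps_any(w, exclude)) next
    }
    seqs <- c(seqs, as.character(Biostrings::subseq(genome[[chr]], s,
                                                    s + width - 1L)))
  }
  blocks <- list(kmer_spectrum = kmer_features(seqs, k = k))
  for (b in setdiff(names(model$blocks), "kmer_spectrum"))
    blocks[[b]] <- matrix(0, length(seqs), ncol(model$blocks[[b]]),
                          dimnames = list(NULL, colnames(model$blocks[[b]])))
  mean(predict(model, blocks)$is_enhancer)
}
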