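#' Composite candidate score for validation prioritization
#'
#' Deterministic surrogate for manual candidate selection: a weighted sum
#' of the stage-1 enhancer decision value (min-max normalized over the
#' cohort), the capped count of TFs with significant binding-site
#' divergence, and three gene-context flags.  The composite is monotone
#' in every component for fixed non-negative weights.
#'
#' @param predictions data frame with \code{region_id}, \code{score1},
#'   \code{tissues_assigned} (e.g. from
#'   \code{\link{predict.enhancer_finder}} plus a region_id column).
#' @param divergence data frame with \code{region_id}, \code{n_sig_tfs}.
#' @param gene_context data frame with \code{region_id} and logical
#'   \code{dev_gene_within_1mb}, \code{tf_nearest},
#'   \code{de_gene_within_1mb}.
#' @param weights numeric length 5 (score1, divergence, dev gene, TF
#'   nearest, DE gene); default \code{c(0.4, 0.3, 0.1, 0.1, 0.1)}.
#' @param cap divergence count cap, default 5.
#' @return data frame sorted by descending \code{composite} (ties by
#'   \code{region_id}), with a \code{rank} column.  The score is a
#'   declared surrogate for expert curation, recorded in the
#'   \code{"selection"} attribute.
#' @export
score_candidates <- function(predictions, divergence, gene_context,
                             weights = c(0.4, 0.3, 0.1, 0.1, 0.1),
                             cap = 5) {
  if (any(weights < 0)) stop("weights must be non-negative")
  ids <- predictions$region_id
  missing_div <- setdiff(ids, divergence$region_id)
  missing_ctx <- setdiff(ids, gene_context$region_id)
  if (length(missing_div) || length(missing_ctx))
    stop("region ids missing from inputs: ",
         paste(unique(c(missing_div, missing_ctx)), collapse = ", "))
  df <- merge(merge(predictions, divergence, by = "region_id"),
              gene_context, by = "region_id")
  rng <- range(df$score1)
  norm1 <- if (diff(rng) > 0) (df$score1 - rng[1]) / diff(rng)
           else rep(0.5, nrow(df))
  df$composite <- weights[1] * norm1 +
    weights[2] * pmin(df$n_sig_tfs, cap) / cap +
    weights[3] * as.numeric(df$dev_gene_within_1mb) +
    weights[4] * as.numeric(df$tf_nearest) +
    weights[5] * as.numeric(df$de_gene_within_1mb)
  df <- df[order(-df$composite, df$region_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "selection") <- "composite surrogate score (not expert curation)"
  df
}

#' Select top candidates under constraints
#'
#' Greedy selection of the \code{n} highest-composite candidates,
#' honouring minimum per-predicted-tissue quotas, plus optional negative
#' controls drawn from the lowest-composite regions.
#'
#' @param scores output of \code{\link{score_candidates}}.
#' @param n number of candidates.
#' @param min_per_tissue named integer vector, e.g. \code{c(brain = 2)}:
#'   minimum selected candidates whose \code{tissues_assigned} contains
#'   the tissue.
#' @param n_negative_controls negative controls appended from the bottom
#'   of the ranking (not counted in \code{n}).
#' @return data frame of selected rows with a \code{role} column
#'   (candidate / negative_control).
#' @export
select_top <- function(scores, n, min_per_tissue = NULL,
                       n_negative_controls = 0) {
  if (n > nrow(scores)) stop("n exceeds number of scored candidates")
  has_tissue <- function(rows, t)
    vapply(strsplit(rows$tissues_assigned, ","), function(x) t %in% x, TRUE)
  picked <- logical(nrow(scores))
  if (!is.null(min_per_tissue)) {
    for (t in names(min_per_tissue)) {
      elig <- which(has_tissue(scores, t) & !picked)
      need <- min_per_tissue[[t]] - sum(has_tissue(scores[picked, ,
                                                          drop = FALSE], t))
      if (need > length(elig))
        stop("infeasible constraint: fewer than ", min_per_tissue[[t]],
             " candidates for tissue ", t)
      if (need > 0) picked[elig[seq_len(need)]] <- TRUE
    }
    if (sum(picked) > n) stop("constraints exceed n")
  }
  picked[which(!picked)[seq_len(n - sum(picked))]] <- TRUE
  sel <- scores[picked, , drop = FALSE]
  sel$role <- "candidate"
  if (n_negative_controls > 0) {
    pool <- scores[!picked, , drop = FALSE]
    if (nrow(pool) < n_negative_controls)
      stop("not enough regions left for negative controls")
    neg <- pool[order(pool$composite, pool$region_id), ,
                drop = FALSE][seq_len(n_negative_controls), ]
    neg$role <- "negative_control"
    sel <- rbind(sel, neg)
  }
  rownames(sel) <- NULL
  sel
}
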