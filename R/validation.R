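## Transgenic LacZ reporter assay calling.
##
## Per-embryo staining observations are tabulated per construct and
## species; activity, confidence and species-difference calls follow
## fixed count-and-consistency rules (three or more embryos with
## consistent staining), mirroring standard annotation practice for
## E11.5 transient transgenic assays.

#' Anatomical domain vocabulary for embryo staining calls
#'
#' The fixed set of E11.5 annotation domains recognised in embryo-call
#' tables.
#' @export
DOMAIN_VOCAB <- c("forebrain", "midbrain", "hindbrain", "neural_tube",
                  "limb", "heart", "eye", "ear", "facial_mesenchyme",
                  "other")

#' Read per-embryo staining calls
#'
#' TSV with header: \code{construct_id}, \code{species} (human/chimp),
#' \code{embryo_id}, \code{domain}, \code{staining} (none/stained),
#' \code{pattern_id}.  Each embryo appears at least once; domains not
#' listed for an embryo are unstained.
#'
#' @param path TSV path.
#' @return data frame of embryo calls.
#' @export
read_embryo_calls <- function(path) {
  calls <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "")
  validate_embryo_calls(calls)
  calls
}

validate_embryo_calls <- function(calls) {
  need <- c("construct_id", "species", "embryo_id", "domain", "staining")
  if (!all(need %in% names(calls)))
    stop("embryo calls need columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(calls$domain), DOMAIN_VOCAB)
  if (length(bad)) stop("unknown domain(s): ", paste(bad, collapse = ", "))
  if (!all(calls$species %in% c("human", "chimp")))
    stop("species must be human or chimp")
  if (!all(calls$staining %in% c("none", "stained")))
    stop("staining must be none or stained")
  if (is.null(calls$pattern_id)) calls$pattern_id <- NA_character_
  invisible(calls)
}

## stained rows of one construct
stained_rows <- function(calls) calls[calls$staining == "stained", ,
                                      drop = FALSE]

#' Call enhancer activity for one construct
#'
#' A domain is active when at least \code{min_embryos} distinct embryos
#' (human and chimpanzee pooled) are stained in it; the construct is an
#' enhancer iff at least one domain is active.
#'
#' @param calls embryo-call rows for a single construct.
#' @param min_embryos embryo support threshold, default 3.
#' @return list: \code{construct_id}, \code{active} flag,
#'   \code{active_domains}, \code{support} (stained-embryo count per
#'   domain).
#' @export
call_activity <- function(calls, min_embryos = 3) {
  stopifnot(length(unique(calls$construct_id)) == 1)
  st <- stained_rows(calls)
  support <- vapply(DOMAIN_VOCAB, function(d)
    length(unique(st$embryo_id[st$domain == d])), 0L)
  active <- names(support)[support >= min_embryos]
  list(construct_id = calls$construct_id[1],
       active = length(active) > 0,
       active_domains = active,
       support = support)
}

#' Classify an active construct as high-confidence or suggestive
#'
#' High confidence requires that within every active domain at least
#' \code{min_embryos} stained embryos share the same within-domain
#' pattern; a construct that is reproducibly active in a domain but with
#' varying patterns across embryos is suggestive.
#'
#' @param result output of \code{\link{call_activity}}.
#' @param calls the construct's embryo-call rows.
#' @param min_embryos threshold, default 3.
#' @return \code{"high_confidence"} or \code{"suggestive"}.
#' @export
classify_confidence <- function(result, calls, min_embryos = 3) {
  if (!result$active) stop("confidence is undefined for negative constructs")
  st <- stained_rows(calls)
  consistent <- vapply(result$active_domains, function(d) {
    pat <- st$pattern_id[st$domain == d]
    pat[is.na(pat)] <- "<none>"
    max(table(pat)) >= min_embryos
  }, TRUE)
  if (all(consistent)) "high_confidence" else "suggestive"
}

## per-species stained / unstained embryo counts and modal pattern in a
## domain
species_domain_support <- function(calls, species, domain) {
  sp <- calls[calls$species == species, , drop = FALSE]
  emb <- unique(sp$embryo_id)
  st <- sp[sp$domain == domain & sp$staining == "stained", , drop = FALSE]
  pat <- st$pattern_id
  pat[is.na(pat)] <- "<none>"
  modal <- if (length(pat)) names(which.max(table(pat))) else NA_character_
  modal_n <- if (length(pat)) max(table(pat)) else 0L
  list(n_embryos = length(emb),
       n_stained = length(unique(st$embryo_id)),
       n_unstained = length(emb) - length(unique(st$embryo_id)),
       modal_pattern = modal, modal_n = modal_n)
}

#' Call a human-chimpanzee activity difference for one construct
#'
#' A domain differs between species when one species has at least
#' \code{min_per_species} embryos stained there with a consistent
#' pattern, and the other species has at least \code{min_per_species}
#' embryos unstained in it (or consistently stained with a different
#' pattern).  The construct is called species-different iff some such
#' domain is high-confidence in the species showing activity.
#'
#' @param calls the construct's embryo-call rows (both species present).
#' @param min_per_species per-species embryo threshold, default 3.
#' @return list: \code{construct_id}, \code{is_difference},
#'   \code{differing_domains}, \code{support} (per-species counts per
#'   differing domain).
#' @export
call_species_difference <- function(calls, min_per_species = 3) {
  stopifnot(length(unique(calls$construct_id)) == 1)
  sp <- unique(calls$species)
  if (!all(c("human", "chimp") %in% sp))
    stop("both species required for a comparison; present: ",
         paste(sp, collapse = ", "))
  differing <- character()
  support <- list()
  for (d in DOMAIN_VOCAB) {
    h <- species_domain_support(calls, "human", d)
    c0 <- species_domain_support(calls, "chimp", d)
    for (onoff in list(list(on = h, off = c0), list(on = c0, off = h))) {
      consistent_on <- onoff$on$modal_n >= min_per_species
      off_absent <- onoff$off$n_unstained >= min_per_species
      off_other <- onoff$off$modal_n >= min_per_species &&
        !identical(onoff$off$modal_pattern, onoff$on$modal_pattern)
      if (consistent_on && (off_absent || off_other)) {
        differing <- c(differing, d)
        support[[d]] <- list(human = h, chimp = c0)
        break
      }
    }
  }
  list(construct_id = calls$construct_id[1],
       is_difference = length(differing) > 0,
       differing_domains = differing, support = support)
}

#' Two-sample t-test on limb stain fractions
#'
#' Compares the fraction of the forelimb stained between embryos
#' carrying the human and the chimpanzee construct.
#'
#' @param human,chimp numeric vectors of stained fractions in [0, 1]
#'   (>= 2 each).
#' @param welch use Welch's unequal-variance test instead of the default
#'   equal-variance Student test.
#' @return list: \code{mean_human}, \code{mean_chimp}, \code{t},
#'   \code{p_two_sided}, \code{df}.
#' @export
limb_fraction_test <- function(human, chimp, welch = FALSE) {
  if (length(human) < 2 || length(chimp) < 2)
    stop("need >= 2 measurements per species")
  if (any(c(human, chimp) < 0 | c(human, chimp) > 1))
    stop("fractions must lie in [0, 1]")
  tt <- stats::t.test(human, chimp, var.equal = !welch)
  list(mean_human = mean(human), mean_chimp = mean(chimp),
       t = unname(tt$statistic), p_two_sided = tt$p.value,
       df = unname(tt$parameter))
}

#' Analyse a whole assay table
#'
#' Applies \code{\link{call_activity}}, \code{\link{classify_confidence}}
#' and \code{\link{call_species_difference}} per construct.
#'
#' @param calls embryo-call data frame (multiple constructs).
#' @param min_embryos pooled-embryo activity threshold.
#' @param min_per_species per-species difference threshold.
#' @return data frame with one row per construct: \code{construct_id},
#'   \code{status} (negative / suggestive / high_confidence),
#'   \code{active_domains} (comma-joined), \code{is_difference},
#'   \code{differing_domains}.
#' @export
analyze_assays <- function(calls, min_embryos = 3, min_per_species = 3) {
  validate_embryo_calls(calls)
  out <- lapply(split(calls, calls$construct_id), function(cc) {
    act <- call_activity(cc, min_embryos)
    status <- if (!act$active) "negative"
              else classify_confidence(act, cc, min_embryos)
    diff <- if (all(c("human", "chimp") %in% cc$species))
      call_species_difference(cc, min_per_species)
    else list(is_difference = NA, differing_domains = character())
    data.frame(construct_id = act$construct_id, status = status,
               active_domains = paste(act$active_domains, collapse = ","),
               is_difference = diff$is_difference,
               differing_domains = paste(diff$differing_domains,
                                         collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

round_half_up <- function(x) floor(x + 0.5)

#' Cohort summary of validation results
#'
#' Counts tested/active/high-confidence/species-different constructs,
#' per-domain activity, agreement with predicted tissues, and (when a
#' ledger of externally tested constructs is supplied) the combined
#' positive fraction.  Percentages are rounded half-up to integers.
#'
#' @param results per-construct table from \code{\link{analyze_assays}}.
#' @param predictions optional data frame \code{construct_id},
#'   \code{predicted_tissues} (comma-joined among brain, limb, heart,
#'   neural_tube, other); enables the predicted-tissue match count.  A
#'   construct matches when it is active in at least one domain mapped to
#'   a predicted tissue (brain covers forebrain, midbrain and hindbrain).
#' @param ledger optional data frame \code{construct_id}, \code{source},
#'   \code{outcome} (positive/negative) of all constructs tested across
#'   studies; this study's constructs should already be included.
#' @return list of counts and percentages.
#' @export
summarize_cohort <- function(results, predictions = NULL, ledger = NULL) {
  if (anyDuplicated(results$construct_id))
    stop("duplicate construct ids")
  active <- results$status != "negative"
  out <- list(
    n_tested = nrow(results),
    n_active = sum(active),
    pct_active = round_half_up(100 * mean(active)),
    n_high_confidence = sum(results$status == "high_confidence"),
    n_species_different = sum(results$is_difference %in% TRUE &
                                results$status == "high_confidence"))
  dom <- strsplit(results$active_domains[active], ",")
  out$per_domain <- vapply(DOMAIN_VOCAB, function(d)
    sum(vapply(dom, function(x) d %in% x, TRUE)), 0L)
  if (!is.null(predictions)) {
    m <- merge(results, predictions, by = "construct_id")
    tissue_domains <- list(
      brain = c("forebrain", "midbrain", "hindbrain"),
      limb = "limb", heart = "heart", neural_tube = "neural_tube",
      other = c("eye", "ear", "facial_mesenchyme", "other"))
    match <- vapply(seq_len(nrow(m)), function(i) {
      pred <- strsplit(m$predicted_tissues[i], ",")[[1]]
      pred <- setdiff(pred, "other")   # specific-tissue predictions only
      if (!length(pred) || m$status[i] == "negative") return(FALSE)
      act <- strsplit(m$active_domains[i], ",")[[1]]
      any(unlist(tissue_domains[pred]) %in% act)
    }, TRUE)
    out$n_predicted_tissue_match <- sum(match)
  }
  if (!is.null(ledger)) {
    if (anyDuplicated(ledger$construct_id))
      stop("duplicate construct ids in ledger")
    out$n_combined_tested <- nrow(ledger)
    out$n_combined_positive <- sum(ledger$outcome == "positive")
    out$pct_combined_positive <-
      round_half_up(100 * mean(ledger$outcome == "positive"))
  }
  out
}
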