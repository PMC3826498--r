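# Brute-force oracles, independent of the package's interval / scanning
# machinery: per-base boolean masks on small toy chromosomes, naive
# per-offset PWM scoring, direct tail summation.

# per-base coverage mask of a region table on one chromosome of length L
base_mask <- function(df, chrom, L) {
  m <- logical(L)
  sel <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sel)))
    m[(sel$start[i] + 1):sel$end[i]] <- TRUE
  m
}

# random interval table on toy chromosomes
random_intervals <- function(n, chroms = c("c1", "c2"), L = 10000,
                             max_len = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len)
}

# naive per-offset, per-strand PWM scoring
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
naive_scan <- function(seq, p, threshold_frac = 0.8) {
  ch <- strsplit(toupper(seq), "")[[1]]
  w <- p$width
  thr <- threshold_frac * sum(apply(p$logodds, 1, max))
  hits <- list()
  score_window <- function(win) {
    if (any(!win %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(p$logodds[cbind(seq_len(w), match(win, c("A", "C", "G", "T")))])
  }
  for (i in seq_len(length(ch) - w + 1)) {
    win <- ch[i:(i + w - 1)]
    sf <- score_window(win)
    if (!is.na(sf) && sf >= thr)
      hits[[length(hits) + 1]] <- data.frame(position = i - 1L,
                                             strand = "+", score = sf)
    rcwin <- rev(unname(COMP[win]))
    sr <- score_window(rcwin)
    if (!is.na(sr) && sr >= thr)
      hits[[length(hits) + 1]] <- data.frame(position = i - 1L,
                                             strand = "-", score = sr)
  }
  if (!length(hits))
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# informative random motif matrix (one dominant base per position)
random_pwm_fixture <- function(width, info = 0.85) {
  m <- matrix((1 - info) / 3, width, 4)
  m[cbind(seq_len(width), sample.int(4, width, replace = TRUE))] <- info
  m
}

# small gene-model collection on toy chromosomes for interval tests
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom = c("c1", "c1", "c1", "c2", "c2"),
    strand = c("+", "-", "+", "+", "-"),
    start = c(1000L, 4000L, 7000L, 2000L, 6000L),
    end = c(2000L, 5000L, 7600L, 3500L, 7000L),
    gene_type = c("protein_coding", "pseudogene", "lincRNA",
                  "protein_coding", "miRNA"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gC", "gD"),
    chrom = c("c1", "c1", "c1", "c2"),
    start = c(1000L, 1500L, 7000L, 2000L),
    end = c(1200L, 1700L, 7200L, 2300L),
    is_coding = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
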