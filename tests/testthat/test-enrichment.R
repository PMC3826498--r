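make_gene_row <- function(id, chrom, tss, strand = "+", span = 2000L) {
  data.frame(gene_id = id, chrom = chrom, strand = strand,
             start = if (strand == "+") tss else tss - span + 1L,
             end = if (strand == "+") tss + span else tss + 1L,
             stringsAsFactors = FALSE)
}

test_that("window association is boundary-inclusive and matches all-pairs oracle", {
  g <- gene_models(rbind(make_gene_row("gIn", "c1", 999999L + 50L),
                         make_gene_row("gOut", "c1", 1000001L + 50L)))
  rs <- region_set("c1", 0, 101, sources = "S", genome_id = "toy")  # midpoint 50
  near <- genes_within(rs, g, window = 1e6)[[1]]
  expect_setequal(near, "gIn")

  set.seed(17)
  genes <- do.call(rbind, lapply(1:50, function(i)
    make_gene_row(sprintf("g%02d", i), sample(c("c1", "c2"), 1),
                  sample.int(5e6, 1))))
  gm <- gene_models(genes)
  df <- random_intervals(100, chroms = c("c1", "c2"), L = 4e6)
  rs2 <- region_set(df$chrom, df$start, df$end, sources = "S",
                    genome_id = "toy")
  W <- 5e5
  res <- genes_within(rs2, gm, window = W)
  mid <- (rs2$start + rs2$end) %/% 2
  for (i in seq_len(nrow(rs2))) {
    oracle <- gm$genes$gene_id[gm$genes$chrom == rs2$chrom[i] &
                                 abs(gm$genes$tss - mid[i]) <= W]
    expect_setequal(res[[i]], oracle)
  }
  # nested growth: result sets are monotone in the window
  res2 <- genes_within(rs2, gm, window = 2 * W)
  for (i in seq_len(nrow(rs2)))
    expect_true(all(res[[i]] %in% res2[[i]]))
})

test_that("nearest gene minimizes |TSS distance| with lexicographic ties", {
  g <- gene_models(rbind(make_gene_row("gB", "c1", 200L),
                         make_gene_row("gA", "c1", 0L)))
  rs <- region_set("c1", 90, 111, sources = "S", genome_id = "toy")  # mid 100
  expect_equal(nearest_gene(rs, g), "gA")  # equidistant, lexicographic
  expect_error(nearest_gene(rs, gene_models(
    make_gene_row("x", "c1", 1L)[0, ])), "empty")

  set.seed(23)
  genes <- do.call(rbind, lapply(1:30, function(i)
    make_gene_row(sprintf("g%02d", i), "c1", sample.int(1e6, 1))))
  gm <- gene_models(genes)
  df <- random_intervals(60, chroms = "c1", L = 9e5)
  rs2 <- region_set(df$chrom, df$start, df$end, sources = "S",
                    genome_id = "toy")
  got <- nearest_gene(rs2, gm)
  mid <- (rs2$start + rs2$end) %/% 2
  for (i in seq_len(nrow(rs2))) {
    d <- abs(gm$genes$tss - mid[i])
    d[gm$genes$tss >= rs2$start[i] & gm$genes$tss < rs2$end[i]] <- 0
    expect_equal(got[i], sort(gm$genes$gene_id[d == min(d)])[1])
  }
})

test_that("tagged-gene proximity counts recover the planted fraction", {
  g <- gene_models(rbind(make_gene_row("g1", "c1", 100L),
                         make_gene_row("g2", "c2", 100L)))
  rs <- region_set(c("c1", "c2"), c(0, 0), c(50, 50), sources = "S",
                   genome_id = "toy")
  expect_equal(category_proximity_counts(rs, g, "TF"), 0)
  g <- tag_genes(g, c("g1", "g2"), "TF")
  expect_equal(category_proximity_counts(rs, g, "TF"), 2)
  expect_error(category_proximity_counts(rs, g, "bogus"), "unknown tag")

  # generator with planted proximity fraction
  set.seed(41)
  f <- 0.3; n <- 500
  gm <- gene_models(make_gene_row("gT", "c1", 500000L))
  gm <- tag_genes(gm, "gT", "developmental")
  near <- runif(n) < f
  start <- ifelse(near, 450000, 2500000) + sample.int(1000, n, TRUE)
  rs2 <- region_set(rep("c1", n), start, start + 100, sources = "S",
                    genome_id = "toy")
  cnt <- category_proximity_counts(rs2, gm, "developmental", window = 1e6)
  expect_equal(cnt, sum(near))
})

test_that("regulatory domains honour basal windows, caps and neighbours", {
  single <- gene_models(make_gene_row("g1", "c1", 2e6L))
  d <- build_regulatory_domains(single)
  expect_equal(d$start, 2e6 - 1e6)
  expect_equal(d$end, 2e6 + 1e6)
  expect_true(d$start <= d$basal_start && d$end >= d$basal_end)

  # two genes 10 kb apart, basal 5 kb: extension stops at the neighbour
  two <- gene_models(rbind(make_gene_row("gL", "c1", 100000L),
                           make_gene_row("gR", "c1", 110000L)))
  d2 <- build_regulatory_domains(two, basal_up = 5000, basal_down = 1000)
  # gL: + strand basal [95000, 101001); gR basal [105000, 111001)
  expect_equal(d2$end[d2$gene_id == "gL"], 105000)   # stops at gR basal
  expect_equal(d2$start[d2$gene_id == "gR"], 101001) # stops at gL basal
  # domains always contain their basal window
  expect_true(all(d2$start <= d2$basal_start & d2$end >= d2$basal_end))
})

test_that("binomial enrichment tail matches direct summation", {
  # n=10, k=5, coverage 0.2: direct summation oracle
  g <- gene_models(make_gene_row("g1", "c1", 0L, span = 1L))
  doms <- data.frame(gene_id = "g1", chrom = "c1", start = 0L,
                     end = 200000L, basal_start = 0L, basal_end = 1L)
  set.seed(1)
  # 5 regions inside the domain, 5 outside
  rs <- region_set(rep("c1", 10),
                   c(seq(1000, 100000, length.out = 5),
                     seq(300000, 900000, length.out = 5)),
                   c(seq(1000, 100000, length.out = 5),
                     seq(300000, 900000, length.out = 5)) + 100,
                   sources = "S", genome_id = "toy")
  res <- term_enrichment(rs, doms, list(T1 = "g1"),
                         background = "whole_genome", genome_size = 1e6)
  expect_equal(res$n_regions_hit, 5)
  expect_equal(res$genome_fraction, 0.2)
  oracle <- sum(choose(10, 5:10) * 0.2^(5:10) * 0.8^(10 - 5:10))
  expect_equal(res$p, oracle, tolerance = 1e-12)

  # a term covering the entire genome has p = 1 for any hit count
  doms_all <- data.frame(gene_id = "g1", chrom = "c1", start = 0L,
                         end = 1000000L, basal_start = 0L, basal_end = 1L)
  expect_equal(term_enrichment(rs, doms_all, list(T1 = "g1"),
                               background = "whole_genome",
                               genome_size = 1e6)$p, 1)
  expect_error(term_enrichment(rs, doms, list(T1 = "gX"),
                               background = "whole_genome",
                               genome_size = 1e6), "zero-coverage")
})

test_that("binomial and hypergeometric tails match exhaustive summation for n <= 25", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:25, 1); k <- sample.int(n, 1); p0 <- runif(1, 0.05, 0.6)
    tail_binom <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - k:n))
    expect_equal(pbinom(k - 1, n, p0, lower.tail = FALSE), tail_binom,
                 tolerance = 1e-10)
    N <- sample(20:60, 1); K <- sample.int(N - 1, 1)
    nn <- sample.int(min(N, 25), 1); kk <- sample.int(min(K, nn), 1)
    tail_hyper <- sum(choose(K, kk:min(K, nn)) *
                        choose(N - K, nn - kk:min(K, nn))) / choose(N, nn)
    expect_equal(phyper(kk - 1, K, N - K, nn, lower.tail = FALSE),
                 tail_hyper, tolerance = 1e-10)
  }
})

test_that("BH q-values dominate p and planted enrichment ranks first", {
  set.seed(5)
  # 20 genes on one 10 Mb chromosome; one term planted
  genes <- do.call(rbind, lapply(1:20, function(i)
    make_gene_row(sprintf("g%02d", i), "c1", i * 500000L)))
  gm <- gene_models(genes)
  doms <- build_regulatory_domains(gm, chrom_lengths = c(c1 = 1.05e7))
  terms <- lapply(1:8, function(i) sample(genes$gene_id, 4))
  names(terms) <- sprintf("T%d", 1:8)
  planted <- "T3"
  target_doms <- doms[doms$gene_id %in% terms[[planted]], ]
  hits <- 0
  for (sim in 1:20) {
    # regions preferentially placed in the planted term's domains
    n <- 80
    in_dom <- runif(n) < 0.6
    pos <- ifelse(in_dom,
                  {
                    row <- target_doms[sample.int(nrow(target_doms), n,
                                                  TRUE), ]
                    row$start + floor(runif(n) * (row$end - row$start - 100))
                  },
                  floor(runif(n) * 1.04e7))
    rs <- region_set(rep("c1", n), pos, pos + 100, sources = "S",
                     genome_id = "toy")
    res <- term_enrichment(rs, doms, terms, background = "whole_genome",
                           genome_size = 1.05e7)
    expect_true(all(res$q >= res$p - 1e-12))
    expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
    if (res$term_id[1] == planted) hits <- hits + 1
  }
  expect_gte(hits, 19)  # planted term ranks first in >= 95 % of sims
})
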