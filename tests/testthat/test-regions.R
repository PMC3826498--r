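test_that("BED reading sorts, validates and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t10\t20\tr1", "chr1\t5\t8\tr2"), f)
  rs <- read_regions(f, source_label = "S")
  expect_equal(nrow(rs), 2)
  expect_equal(rs$start, c(5L, 10L))
  expect_equal(unlist(rs$sources), c("S", "S"))

  writeLines(character(), f)
  expect_equal(nrow(read_regions(f, "S")), 0)

  writeLines("chr1\t20\t10", f)
  expect_error(read_regions(f, "S"), "line 1")
  writeLines(c("chr1\t1\t5", "chr1\tx\t9"), f)
  expect_error(read_regions(f, "S"), "line 2")
  expect_error(read_regions(file.path(tempdir(), "nope.bed"), "S"),
               "does not exist")
})

test_that("merging collapses overlapping and bookended intervals and pools sources", {
  a <- region_set("chr1", 0, 10, sources = "A", genome_id = "g")
  b <- region_set("chr1", 5, 15, sources = "B", genome_id = "g")
  m <- merge_region_sets(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0L, 15L))
  expect_equal(m$sources[[1]], c("A", "B"))

  # bookended intervals merge; disjoint ones survive
  d <- merge_region_sets(list(region_set("chr1", c(0, 10), c(10, 20),
                                         sources = "A", genome_id = "g")))
  expect_equal(nrow(d), 1)
  e <- merge_region_sets(list(region_set("chr1", c(0, 50), c(10, 60),
                                         sources = "A", genome_id = "g")))
  expect_equal(nrow(e), 2)

  expect_error(merge_region_sets(list(
    region_set("chr1", 0, 5, sources = "A", genome_id = "g1"),
    region_set("chr1", 0, 5, sources = "B", genome_id = "g2"))),
    "mixed genome_id")
})

test_that("merge matches the per-base union oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:3) {
    sets <- lapply(1:4, function(s) {
      df <- random_intervals(50, chroms = "c1", L = 10000)
      region_set(df$chrom, df$start, df$end, sources = paste0("s", s),
                 genome_id = "toy")
    })
    m <- merge_region_sets(sets)
    mask <- Reduce(`|`, lapply(sets, base_mask, chrom = "c1", L = 10000))
    expect_equal(base_mask(m, "c1", 10000), mask)
    expect_equal(sum(region_widths(m)), sum(mask))
    # idempotence: merging the merged set changes nothing
    m2 <- merge_region_sets(list(m))
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
    # no overlapping or touching survivors
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})

test_that("coding filter drops >=1 bp overlaps, keeps abutting regions", {
  genes <- toy_genes()  # coding exons: c1 1000-1200, c2 2000-2300
  rs <- region_set("c1", c(900, 1200, 1199), c(1100, 1300, 1200),
                   name = c("hit", "abut", "edge"), sources = "S",
                   genome_id = "toy")
  out <- filter_coding(rs, genes)
  expect_setequal(out$name, "abut")
  expect_setequal(attr(out, "dropped"), c("hit", "edge"))
  # empty input passes through
  expect_equal(nrow(filter_coding(region_set(genome_id = "toy"), genes)), 0)
})

test_that("coding filter agrees with the per-base overlap oracle", {
  set.seed(7)
  genes <- toy_genes()
  df <- random_intervals(200, chroms = c("c1", "c2"), L = 9000)
  rs <- region_set(df$chrom, df$start, df$end, sources = "S",
                   genome_id = "toy")
  out <- filter_coding(rs, genes)
  cod <- genes$exons[genes$exons$is_coding, ]
  for (chr in c("c1", "c2")) {
    cmask <- base_mask(cod, chr, 10000)
    keep_oracle <- vapply(which(rs$chrom == chr), function(i)
      !any(cmask[(rs$start[i] + 1):rs$end[i]]), TRUE)
    expect_equal(rs$name[rs$chrom == chr][keep_oracle],
                 out$name[out$chrom == chr])
  }
})

test_that("context classification applies the fixed precedence and partitions", {
  genes <- toy_genes()
  rs <- region_set("c1", c(1800, 4100, 7050, 100),
                   c(1900, 4200, 7150, 200),
                   name = c("intron", "pseudo", "linc", "inter"),
                   sources = "S", genome_id = "toy")
  expect_equal(classify_context(rs, genes),
               c("inter" = "intergenic", "intron" = "intronic",
                 "pseudo" = "pseudogene", "linc" = "lincRNA_exon")[rs$name],
               ignore_attr = TRUE)
  # pseudogene wins over intronic when a region overlaps both
  g2 <- toy_genes()
  g2$genes$start[g2$genes$gene_id == "gB"] <- 1500L  # overlap gA span
  both <- region_set("c1", 1850, 1950, name = "b", sources = "S",
                     genome_id = "toy")
  expect_equal(classify_context(both, g2), "pseudogene")
})

test_that("context labels match an independent per-class oracle on random regions", {
  set.seed(11)
  genes <- toy_genes()
  df <- random_intervals(500, chroms = c("c1", "c2"), L = 9000)
  rs <- region_set(df$chrom, df$start, df$end, sources = "S",
                   genome_id = "toy")
  lab <- classify_context(rs, genes)
  g <- genes$genes
  ov <- function(i, tab) {
    any(tab$chrom == rs$chrom[i] & tab$start < rs$end[i] &
          tab$end > rs$start[i])
  }
  oracle <- vapply(seq_len(nrow(rs)), function(i) {
    if (ov(i, g[grepl("pseudogene", g$gene_type), ])) return("pseudogene")
    linc <- merge(genes$exons, g[g$gene_type == "lincRNA", "gene_id",
                                 drop = FALSE], by = "gene_id")
    if (ov(i, linc)) return("lincRNA_exon")
    if (ov(i, g[g$gene_type == "miRNA", ])) return("miRNA")
    if (ov(i, g[g$gene_type == "protein_coding", ])) return("intronic")
    "intergenic"
  }, "")
  expect_equal(lab, oracle)
  expect_equal(sum(table(lab)), nrow(rs))  # partition
})

test_that("TSS distance is signed, zero on containment, and matches linear scan", {
  tss <- data.frame(chrom = "c1", pos = c(150L, 1150L))
  inside <- region_set("c1", 100, 200, sources = "S", genome_id = "toy")
  expect_equal(tss_distance(inside, tss), 0)
  far <- region_set("c1", 100, 201, sources = "S", genome_id = "toy")
  # midpoint 150; nearest TSS among {150 (inside -> 0)}: containment wins
  expect_equal(tss_distance(far, tss), 0)
  only_right <- region_set("c1", 100, 200, sources = "S", genome_id = "toy")
  expect_equal(tss_distance(only_right,
                            data.frame(chrom = "c1", pos = 1150L)), 1000)
  expect_equal(tss_distance(only_right,
                            data.frame(chrom = "c1", pos = 50L)), -100)
  expect_error(tss_distance(only_right, data.frame(chrom = character(),
                                                   pos = integer())),
               "empty")

  set.seed(3)
  df <- random_intervals(100, chroms = "c1", L = 9000)
  rs <- region_set(df$chrom, df$start, df$end, sources = "S",
                   genome_id = "toy")
  tss2 <- data.frame(chrom = "c1", pos = sample.int(10000, 20))
  d <- tss_distance(rs, tss2)
  mid <- (rs$start + rs$end) %/% 2
  for (i in seq_len(nrow(rs))) {
    dd <- tss2$pos - mid[i]
    contained <- any(tss2$pos >= rs$start[i] & tss2$pos < rs$end[i])
    expected <- if (contained) 0 else dd[which.min(abs(dd))]
    expect_equal(d[i], expected)
  }
})

test_that("region summaries report counts, moments and unit fractions", {
  one <- region_set("c1", 0, 100, sources = "S", genome_id = "toy")
  s <- summarize_regions(one)
  expect_equal(s$n, 1)
  expect_equal(s$mean_length, 100)
  expect_equal(s$sd_length, 0)
  empty <- summarize_regions(region_set(genome_id = "toy"))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_length))

  set.seed(5)
  df <- random_intervals(400, chroms = "c1", L = 9000, max_len = 300)
  rs <- region_set(df$chrom, df$start, df$end, sources = "S",
                   genome_id = "toy")
  s2 <- summarize_regions(rs, genes = toy_genes(),
                          tss = data.frame(chrom = "c1", pos = 5000L))
  expect_equal(s2$mean_length, mean(df$end - df$start))
  expect_equal(sum(s2$context_fractions), 1)
  # uniform lengths 1..300: mean 150.5, SE = sd/sqrt(n)
  expect_lt(abs(s2$mean_length - 150.5),
            3 * stats::sd(df$end - df$start) / sqrt(400))
})

test_that("merge-then-filter commutes with filter-then-merge on clean sets", {
  set.seed(21)
  genes <- toy_genes()
  sets <- lapply(1:3, function(s) {
    df <- random_intervals(40, chroms = c("c1", "c2"), L = 9000)
    region_set(df$chrom, df$start, df$end, sources = paste0("s", s),
               genome_id = "toy")
  })
  a <- filter_coding(merge_region_sets(sets), genes)
  b <- merge_region_sets(lapply(sets, filter_coding, genes = genes))
  # compare covered-base masks, excluding merges straddling coding exons
  cod <- genes$exons[genes$exons$is_coding, ]
  for (chr in c("c1", "c2")) {
    ma <- base_mask(a, chr, 10000)
    mb <- base_mask(b, chr, 10000)
    # b may retain fragments whose merged parent touched an exon; a is
    # always a subset of b
    expect_true(all(!ma | mb))
  }
})
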