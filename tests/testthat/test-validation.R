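mk_calls <- function(cid, species, embryos, domain, pattern = "p1",
                     staining = "stained") {
  data.frame(construct_id = cid, species = species,
             embryo_id = paste0(species, "_", embryos), domain = domain,
             staining = staining, pattern_id = pattern,
             stringsAsFactors = FALSE)
}

test_that("the three-embryo rule pools species and gates activity", {
  two <- rbind(mk_calls("c1", "human", 1:2, "forebrain"),
               mk_calls("c1", "chimp", 1:2, "other", staining = "none",
                        pattern = NA))
  expect_false(call_activity(two)$active)
  three <- rbind(mk_calls("c1", "human", 1:2, "forebrain"),
                 mk_calls("c1", "chimp", 1, "forebrain"))
  act <- call_activity(three)
  expect_true(act$active)
  expect_equal(act$active_domains, "forebrain")
  # a stained embryo can only help: adding one never deactivates a domain
  four <- rbind(three, mk_calls("c1", "chimp", 2, "forebrain"))
  expect_equal(call_activity(four)$active_domains, "forebrain")
})

test_that("activity calls match a count-and-threshold oracle on random tables", {
  set.seed(47)
  for (rep in 1:10) {
    rows <- do.call(rbind, lapply(1:8, function(e) {
      doms <- sample(DOMAIN_VOCAB, sample(0:3, 1))
      sp <- if (e <= 4) "human" else "chimp"
      if (!length(doms))
        return(mk_calls("cX", sp, e, "other", staining = "none",
                        pattern = NA))
      mk_calls("cX", sp, e, doms)
    }))
    act <- call_activity(rows, min_embryos = 3)
    st <- rows[rows$staining == "stained", ]
    oracle <- vapply(DOMAIN_VOCAB, function(d)
      length(unique(st$embryo_id[st$domain == d])), 0L)
    expect_equal(unname(act$support), unname(oracle))
    expect_equal(act$active, any(oracle >= 3))
    expect_setequal(act$active_domains, names(oracle)[oracle >= 3])
  }
})

test_that("confidence requires a shared within-domain pattern", {
  same <- rbind(mk_calls("c1", "human", 1:2, "forebrain"),
                mk_calls("c1", "chimp", 1:2, "forebrain"))
  act <- call_activity(same)
  expect_equal(classify_confidence(act, same), "high_confidence")
  varied <- rbind(mk_calls("c1", "human", 1:2, "forebrain",
                           pattern = c("pA", "pB")),
                  mk_calls("c1", "chimp", 1:2, "forebrain",
                           pattern = c("pC", "pD")))
  act2 <- call_activity(varied)
  expect_equal(classify_confidence(act2, varied), "suggestive")
  neg <- mk_calls("c1", "human", 1, "other", staining = "none",
                  pattern = NA)
  expect_error(classify_confidence(call_activity(neg), neg), "negative")
})

test_that("species differences need consistent activity in one species and absence in the other", {
  # chimp 4/4 stained, human 0/5 unstained in one domain
  calls <- rbind(mk_calls("c1", "chimp", 1:4, "forebrain"),
                 mk_calls("c1", "human", 1:5, "other", staining = "none",
                          pattern = NA))
  d <- call_species_difference(calls)
  expect_true(d$is_difference)
  expect_equal(d$differing_domains, "forebrain")

  # both species stained with the same pattern: no difference
  both <- rbind(mk_calls("c2", "chimp", 1:4, "forebrain"),
                mk_calls("c2", "human", 1:4, "forebrain"))
  expect_false(call_species_difference(both)$is_difference)

  # same domain, consistently different patterns: difference
  pat <- rbind(mk_calls("c3", "chimp", 1:4, "forebrain", pattern = "pX"),
               mk_calls("c3", "human", 1:4, "forebrain", pattern = "pY"))
  expect_true(call_species_difference(pat)$is_difference)

  # fewer than three embryos in one species: no call
  thin <- rbind(mk_calls("c4", "chimp", 1:2, "forebrain"),
                mk_calls("c4", "human", 1:4, "other", staining = "none",
                         pattern = NA))
  expect_false(call_species_difference(thin)$is_difference)
  expect_error(call_species_difference(mk_calls("c5", "human", 1:3,
                                                "limb")), "both species")
})

test_that("species-difference calls match a per-domain threshold oracle", {
  set.seed(59)
  for (rep in 1:10) {
    rows <- do.call(rbind, lapply(1:8, function(e) {
      sp <- if (e <= 4) "human" else "chimp"
      doms <- sample(c("forebrain", "limb"), sample(0:2, 1))
      if (!length(doms))
        return(mk_calls("cX", sp, e, "other", staining = "none",
                        pattern = NA))
      mk_calls("cX", sp, e, doms, pattern = sample(c("p1", "p2"), 1))
    }))
    got <- call_species_difference(rows, min_per_species = 3)
    oracle_dom <- Filter(function(d) {
      st <- rows[rows$staining == "stained" & rows$domain == d, ]
      pat <- function(sp) {
        t <- table(st$pattern_id[st$species == sp])
        if (!length(t)) c(n = 0L) else
          setNames(max(t), names(which.max(t)))
      }
      n_emb <- function(sp) length(unique(rows$embryo_id[rows$species == sp]))
      n_st <- function(sp) length(unique(st$embryo_id[st$species == sp]))
      check <- function(on, off) {
        pon <- pat(on)
        poff <- pat(off)
        unname(pon) >= 3 &&
          ((n_emb(off) - n_st(off)) >= 3 ||
             (unname(poff) >= 3 && !identical(names(poff), names(pon))))
      }
      check("human", "chimp") || check("chimp", "human")
    }, DOMAIN_VOCAB)
    expect_setequal(got$differing_domains, oracle_dom)
  }
})

test_that("limb fraction t-test matches the closed-form statistic", {
  same <- limb_fraction_test(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)

  h <- c(0.2, 0.25, 0.3); c0 <- c(0.7, 0.75, 0.8)
  got <- limb_fraction_test(h, c0)
  # independent textbook computation of the pooled-variance t
  sp2 <- (2 * var(h) + 2 * var(c0)) / 4
  t_oracle <- (mean(h) - mean(c0)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(got$t, t_oracle, tolerance = 1e-10)
  expect_equal(got$p_two_sided, p_oracle, tolerance = 1e-10)
  # location invariance of the difference
  shifted <- limb_fraction_test(h + 0.1, c0 + 0.1)
  expect_equal(shifted$t, got$t, tolerance = 1e-10)
  expect_error(limb_fraction_test(0.5, c0), ">= 2")
  expect_error(limb_fraction_test(c(2, 3), c0), "\\[0, 1\\]")

  set.seed(67)
  for (rep in 1:10) {
    a <- runif(sample(3:8, 1)); b <- runif(sample(3:8, 1))
    got <- limb_fraction_test(a, b)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_o <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(got$t, t_o, tolerance = 1e-10)
  }
})

test_that("cohort summaries are deterministic and embryo-order invariant", {
  calls <- load_assay_calls()
  res1 <- analyze_assays(calls)
  set.seed(3)
  res2 <- analyze_assays(calls[sample.int(nrow(calls)), ])
  res2 <- res2[match(res1$construct_id, res2$construct_id), ]
  rownames(res2) <- NULL
  expect_equal(res1, res2)
  s <- summarize_cohort(res1)
  expect_equal(s$n_tested, 29)
  expect_gte(s$n_active, s$n_high_confidence)
  dup <- rbind(res1, res1[1, ])
  expect_error(summarize_cohort(dup), "duplicate")
  empty <- res1[0, ]
  expect_equal(summarize_cohort(empty)$n_tested, 0)
})
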