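test_that("motif scanning reports overlapping occurrences and filters by disorder rate", {
  ps <- protein_set(c("hi", "lo"), c("QAQAQ", "QAQAQ"))
  profs <- list(hi = flat_profile("hi", 5, 0.9),
                lo = disorder_profile(score_track("lo", c(0.9, 0.9, 0.1, 0.1, 0.1))))
  cls <- motif_classes("M1", "Q.Q", "PPI")
  hits <- scan_motifs(ps, cls, profs)
  # disorder rate 0.4 protein contributes nothing; overlapping matches both kept
  expect_equal(hits$protein_id, c("hi", "hi"))
  expect_equal(hits$start, c(1, 3))
  expect_equal(hits$end, c(3, 5))
  expect_equal(hits$matched, c("QAQ", "QAQ"))

  expect_error(scan_motifs(ps, cls, profs["hi"]), "no disorder profile")

  # per-hit disordered-fraction filter
  profs$lo <- disorder_profile(score_track("lo", c(0.9, 0.9, 0.9, 0.1, 0.1)))
  hits <- scan_motifs(ps, cls, profs, require_disordered_fraction = 1)
  expect_equal(hits$protein_id[hits$start == 1], c("hi", "lo"))
  expect_false(any(hits$protein_id == "lo" & hits$start == 3))
})

test_that("scanning equals the anchored-regex oracle on random sequences", {
  withr::with_seed(41, {
    pats <- c("Q.Q", "[ST]P", "K{2,3}A", "P.[ED]K")
    for (i in 1:15) {
      s <- random_aa_seq(300, letters = c("Q", "A", "S", "T", "P", "K", "E", "D"))
      ps <- protein_set("p", s)
      profs <- list(p = flat_profile("p", 300, 0.9))
      for (pat in pats) {
        got <- scan_motifs(ps, motif_classes("m", pat), profs)
        exp <- oracle_scan(s, pat)
        expect_equal(got$start, exp$start)
        expect_equal(got$end, exp$end)
      }
    }
  })
})

test_that("permutation-mode null conserves the residue multiset exactly", {
  withr::with_seed(43, pool <- sample(AA_ALPHABET, 120, replace = TRUE))
  nul <- build_null(pool, n_constructs = 3, construct_length = 40, seed = 9,
                    mode = "permute")
  shuffled <- strsplit(paste(nul$constructs, collapse = ""), "")[[1]]
  expect_equal(sort(shuffled), sort(pool))
  expect_equal(nchar(nul$constructs), rep(40, 3))
  # auto picks permute on exact size match
  nul2 <- build_null(pool, 3, 40, seed = 9)
  expect_equal(nul2$mode, "permute")
  expect_error(build_null(pool, 2, 41, seed = 1, mode = "permute"),
               "pool size")
})

test_that("null ensembles are reproducible per seed and follow the stated geometry", {
  withr::with_seed(47, pool <- sample(AA_ALPHABET, 2000, replace = TRUE,
                                      prob = aa_composition_disordered))
  n1 <- build_null(pool, seed = 5)
  n2 <- build_null(pool, seed = 5)
  expect_identical(n1$constructs, n2$constructs)
  expect_equal(n1$n_constructs, 20L)
  expect_equal(n1$construct_length, 10000L)
  expect_equal(unique(nchar(n1$constructs)), 10000L)
  expect_equal(n1$mode, "resample")
  n3 <- build_null(pool, seed = 6)
  expect_false(identical(n1$constructs, n3$constructs))
  expect_warning(build_null(c("A", "C"), 1, 10, seed = 1), "unstable")
})

test_that("density statistics follow 1000 * hits / residues", {
  d <- motif_density(50, 25000)
  expect_equal(d$density_per_kaa, 2.0)
  expect_equal(motif_density(0, 1000)$density_per_kaa, 0)
  expect_error(motif_density(3, 0), ">= 1")
  withr::with_seed(51, {
    for (i in 1:10) {
      h <- sample(0:500, 1); n <- sample(1:100000, 1)
      expect_equal(motif_density(h, n)$density_per_kaa, 1000 * h / n)
    }
  })
})

test_that("enrichment test matches the closed-form one-sample t and empirical p", {
  nd <- c(0.5, 0.6, 0.7)
  res <- enrichment_test(10, nd, mode = "one_sample")
  expect_equal(res$empirical_p, 1 / 4)

  # observed equal to the null mean
  res <- enrichment_test(0.6, nd, mode = "one_sample")
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # closed-form oracle at the reported scale (null ~ 0.645, observed > 2)
  withr::with_seed(53, nd <- rnorm(20, 0.645, 0.12))
  res <- enrichment_test(2.0, nd, mode = "one_sample")
  t_exp <- (mean(nd) - 2.0) / (sd(nd) / sqrt(20))
  expect_equal(res$t, t_exp)
  expect_equal(res$df, 19)
  expect_equal(res$p, 2 * stats::pt(-abs(t_exp), 19))
  expect_lt(res$p, 1e-4)

  # two-sample mode equals Welch on the two density vectors
  withr::with_seed(57, obs <- rnorm(8, 1.78, 0.3))
  res2 <- enrichment_test(obs, nd, mode = "two_sample")
  tt <- t.test(obs, nd)
  expect_equal(res2$t, unname(tt$statistic))
  expect_equal(res2$p, tt$p.value)

  expect_warning(res3 <- enrichment_test(1, c(0.5, 0.5, 0.5), "one_sample"),
                 "constant null")
  expect_true(is.na(res3$t))
  expect_equal(res3$empirical_p, 1 / 4)
})

test_that("tag filtering selects classes and hits carrying the tag", {
  cls <- motif_classes(c("a", "b", "c"), c("Q", "K", "P"),
                       tags = c("PPI,nuclear", "PPI", "modification"))
  expect_equal(filter_by_tag(cls, "PPI")$id, c("a", "b"))
  expect_equal(filter_by_tag(cls, "nuclear")$id, "a")
  expect_warning(sub <- filter_by_tag(cls, "cytoplasmic"), "no motif class")
  expect_equal(nrow(sub), 0)

  hits <- data.frame(motif_id = c("a", "b", "c"), protein_id = "p",
                     start = 1:3, end = 1:3, matched = c("Q", "K", "P"))
  expect_equal(filter_by_tag(hits, "PPI", cls)$motif_id, c("a", "b"))
})

test_that("null construct density converges to the i.i.d. occurrence probability", {
  # fixed two-letter composition; pattern QK has analytic per-position
  # match probability fQ * fK under the i.i.d. model
  withr::with_seed(59, pool <- sample(c("Q", "K", "A"), 5000, replace = TRUE,
                                      prob = c(0.3, 0.3, 0.4)))
  nul <- build_null(pool, n_constructs = 40, construct_length = 2000, seed = 61)
  cls <- motif_classes("qk", "QK")
  dens <- null_densities(nul, cls)
  comp <- as.numeric(nul$source_composition) / sum(nul$source_composition)
  names(comp) <- names(nul$source_composition)
  p_match <- comp["Q"] * comp["K"]
  expected <- 1000 * p_match * (2000 - 1) / 2000
  mc_se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - expected), 3 * mc_se + 1e-9)
})
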