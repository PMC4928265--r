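test_that("candidate calling applies the 8-residue floor at the boundary", {
  v <- rep(0.1, 40)
  v[11:18] <- 0.9   # run of exactly 8 -> kept
  v[25:31] <- 0.9   # run of 7 -> dropped
  cand <- candidate_binding_regions(binding_profile(score_track("p", v)))
  expect_equal(cand$start, 11)
  expect_equal(cand$end, 18)
  expect_equal(nrow(candidate_binding_regions(
    binding_profile(score_track("p", rep(0.2, 30))))), 0)

  # run-length oracle on random profiles
  withr::with_seed(79, {
    for (i in 1:15) {
      v <- runif(200)
      min_len <- sample(2:10, 1)
      got <- candidate_binding_regions(binding_profile(score_track("p", v)),
                                       min_len = min_len)
      exp <- oracle_runs(v >= 0.5, min_len = min_len)
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
    }
  })
})

test_that("conservation intersection keeps >= min-length conserved sub-runs", {
  mk_track <- function(cons_pos, L = 150) {
    sc <- rep(0.2, L)
    sc[cons_pos] <- 0.95
    structure(data.frame(residue = 1:L, column = 1:L, seq_cons = sc,
                         dis_cons = rep(1, L)),
              class = c("conservation_track", "data.frame"))
  }
  cand <- regions("p", 100, 120, "BINDING_CANDIDATE")
  got <- conserved_binding_regions(cand, mk_track(105:112))
  expect_equal(got$start, 105)
  expect_equal(got$end, 112)
  expect_equal(got$parent_start, 100)

  expect_equal(nrow(conserved_binding_regions(cand, mk_track(integer(0)))), 0)
  # fully conserved candidate comes back unchanged
  got <- conserved_binding_regions(cand, mk_track(1:150))
  expect_equal(got[, c("start", "end")], data.frame(start = 100, end = 120),
               ignore_attr = TRUE)
  # sub-run of 7 < 8 dropped
  expect_equal(nrow(conserved_binding_regions(cand, mk_track(105:111))), 0)
  # coverage error
  short <- structure(data.frame(residue = 1:50, column = 1:50,
                                seq_cons = rep(1, 50), dis_cons = rep(1, 50)),
                     class = c("conservation_track", "data.frame"))
  expect_error(conserved_binding_regions(cand, short), "outside")

  # whole-region mode keeps or drops entire candidates by mean conservation
  got <- conserved_binding_regions(cand, mk_track(101:120), mode = "whole_region")
  expect_equal(got$start, 100)
  expect_equal(got$end, 120)
  expect_equal(nrow(conserved_binding_regions(cand, mk_track(105:112),
                                              mode = "whole_region")), 0)
})

test_that("conservation intersection equals the residue-set oracle and is idempotent", {
  withr::with_seed(83, {
    for (i in 1:10) {
      L <- 300
      sc <- runif(L)
      tr <- structure(data.frame(residue = 1:L, column = 1:L, seq_cons = sc,
                                 dis_cons = rep(1, L)),
                      class = c("conservation_track", "data.frame"))
      st <- sort(sample(1:250, 4))
      cand <- regions("p", st, pmin(st + sample(10:40, 4, replace = TRUE), L),
                      "BINDING_CANDIDATE")
      cand <- cand[!duplicated(cand$start), ]
      got <- conserved_binding_regions(cand, tr, seq_thr = 0.6,
                                       min_conserved_run = 5)
      # oracle: per candidate, brute-force scan of the conserved mask
      exp_list <- list()
      for (k in seq_len(nrow(cand))) {
        span <- cand$start[k]:cand$end[k]
        runs <- oracle_runs(sc[span] >= 0.6, min_len = 5)
        if (nrow(runs) > 0) {
          runs$start <- runs$start + cand$start[k] - 1L
          runs$end <- runs$end + cand$start[k] - 1L
          exp_list[[length(exp_list) + 1]] <- runs
        }
      }
      exp <- if (length(exp_list)) do.call(rbind, exp_list) else
        data.frame(start = integer(0), end = integer(0))
      exp <- exp[order(exp$start), ]
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      # output residues are conserved and inside candidates
      for (k in seq_len(nrow(got))) {
        expect_true(all(sc[got$start[k]:got$end[k]] >= 0.6))
      }
      # idempotence on its own output
      if (nrow(got) > 0) {
        again <- conserved_binding_regions(
          regions(got$protein_id, got$start, got$end, "BINDING_CANDIDATE"),
          tr, seq_thr = 0.6, min_conserved_run = 5)
        expect_equal(again$start, got$start)
        expect_equal(again$end, got$end)
      }
    }
  })
})

test_that("variant mapping respects interval boundaries and matches a double loop", {
  reg <- regions("dot1l", 408, 416, "CONSERVED_BINDING")
  vars <- data.frame(protein_id = c("dot1l", "dot1l", "other"),
                     position = c(410, 407, 410),
                     annotation = "cancer_db")
  res <- map_variants(reg, vars)
  expect_equal(res$regions$n_variants, 1)
  expect_equal(res$assignments$position, 410)
  expect_equal(res$unmapped$position, c(407, 410))

  withr::with_seed(89, {
    for (i in 1:10) {
      st <- sample(1:200, 6, replace = TRUE)
      reg <- regions(sample(c("a", "b"), 6, replace = TRUE), st,
                     st + sample(0:30, 6, replace = TRUE), "BINDING_CANDIDATE")
      vars <- data.frame(protein_id = sample(c("a", "b"), 25, replace = TRUE),
                         position = sample(1:230, 25, replace = TRUE),
                         annotation = NA_character_)
      res <- map_variants(reg, vars)
      exp_counts <- integer(nrow(reg))
      exp_unmapped <- rep(TRUE, nrow(vars))
      for (r in seq_len(nrow(reg))) for (v in seq_len(nrow(vars))) {
        if (vars$protein_id[v] == reg$protein_id[r] &&
            vars$position[v] >= reg$start[r] && vars$position[v] <= reg$end[r]) {
          exp_counts[r] <- exp_counts[r] + 1L
          exp_unmapped[v] <- FALSE
        }
      }
      expect_equal(res$regions$n_variants, exp_counts)
      expect_equal(nrow(res$unmapped), sum(exp_unmapped))
    }
  })
})

test_that("interval overlap reproduces the shared-residue formula", {
  # the ternary-complex helix vs its conserved binding site
  a <- regions("mll1", 2844, 2857, "CUSTOM")
  b <- regions("mll1", 2841, 2853, "CONSERVED_BINDING")
  res <- region_overlap(a, b)
  expect_true(res$overlaps)
  expect_equal(res$shared_residues, 10)

  # the lysine-rich region vs the conserved site
  a <- regions("dot1l", 387, 416, "CUSTOM")
  b <- regions("dot1l", 408, 416, "CONSERVED_BINDING")
  expect_equal(region_overlap(a, b)$shared_residues, 9)

  res <- region_overlap(regions("p", 1, 5, "IDR"), regions("p", 6, 9, "IDR"))
  expect_false(res$overlaps)
  expect_equal(res$shared_residues, 0)

  expect_error(region_overlap(regions("p1", 1, 5, "IDR"),
                              regions("p2", 1, 5, "IDR")), "different proteins")
})

test_that("the binding stand-in scores disordered interface-rich segments high", {
  s <- paste0(strrep("EGSD", 15), strrep("WYLF", 6), strrep("EGSD", 15))
  dis <- rep(0.9, nchar(s))
  prof <- predict_binding_standin(s, dis, "p")
  core <- 65:80
  flank <- 1:40
  expect_gt(mean(prof$track$values[core]), mean(prof$track$values[flank]))
  # same composition but ordered: scores collapse
  prof_ord <- predict_binding_standin(s, rep(0.05, nchar(s)), "p")
  expect_lt(mean(prof_ord$track$values[core]), mean(prof$track$values[core]))
})
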