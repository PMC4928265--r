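test_that("column conservation scoring follows the normalized JSD formula", {
  # column distributed like the background scores 0
  col <- rep(AA_ALPHABET, 2)
  expect_equal(column_jsd(col), 0, tolerance = 1e-12)

  # all-A column against uniform background equals the direct formula,
  # normalized by the point-mass maximum (so it reaches exactly 1)
  colA <- rep("A", 10)
  q <- rep(1 / 20, 20)
  pA <- c(1, rep(0, 19))
  raw <- oracle_jsd2(pA, q)
  expect_equal(column_jsd(colA), raw / raw)
  expect_equal(column_jsd(colA), 1)

  # mixed column: direct evaluation
  col <- c(rep("A", 6), rep("K", 4))
  p <- numeric(20); names(p) <- sort(AA_ALPHABET)
  p["A"] <- 0.6; p["K"] <- 0.4
  expect_equal(column_jsd(col), oracle_jsd2(unname(p), q) / raw)

  # gap handling
  expect_equal(column_jsd(c("A", "A", "-", "-", "-")), 0)
  expect_error(column_jsd(c("-", "-")), "all-gap")
})

test_that("identical fully disordered alignments give maximal conservation", {
  rows <- setNames(rep(strrep("QPES", 10), 5), c("ref", paste0("o", 1:4)))
  aln <- ortholog_alignment(rows, "ref")
  profs <- setNames(lapply(names(rows), function(rn) flat_profile(rn, 40, 0.9)),
                    names(rows))
  tr <- conservation_track(aln, profs)
  expect_equal(nrow(tr), 40)
  expect_equal(tr$seq_cons, rep(1, 40))
  expect_equal(tr$dis_cons, rep(1, 40))
  cls <- classify_disorder_conservation(tr, profs$ref)
  expect_equal(unique(cls), "CONSTRAINED_DISORDER")
})

test_that("reference-gap columns are dropped from the track", {
  rows <- c(ref = "AC-DF", o1 = "ACKDF", o2 = "ACKD-")
  aln <- ortholog_alignment(rows, "ref")
  profs <- list(ref = flat_profile("ref", 4, 0.9),
                o1 = flat_profile("o1", 5, 0.9),
                o2 = flat_profile("o2", 4, 0.9))
  tr <- conservation_track(aln, profs)
  expect_equal(nrow(tr), 4)
  expect_equal(tr$residue, 1:4)
  expect_equal(tr$column, c(1, 2, 4, 5))
  expect_error(conservation_track(aln, profs[c("ref", "o1")]), "no disorder profile")
})

test_that("row order does not change the track and duplicating a row never lowers seq_cons", {
  withr::with_seed(67, {
    ref <- random_aa_seq(60, c("Q", "P", "E", "S", "K", "A"))
    mut <- function() {
      ch <- strsplit(ref, "")[[1]]
      ix <- sample(60, 15)
      ch[ix] <- sample(AA_ALPHABET, 15, replace = TRUE)
      paste(ch, collapse = "")
    }
    rows <- c(ref = ref, o1 = mut(), o2 = mut(), o3 = mut())
    profs <- setNames(lapply(names(rows), function(rn) flat_profile(rn, 60, 0.9)),
                      names(rows))
    aln1 <- ortholog_alignment(rows, "ref")
    aln2 <- ortholog_alignment(rows[c("o2", "ref", "o3", "o1")], "ref")
    tr1 <- conservation_track(aln1, profs)
    tr2 <- conservation_track(aln2, profs)
    expect_equal(tr1$seq_cons, tr2$seq_cons)
    expect_equal(tr1$dis_cons, tr2$dis_cons)

    rows_dup <- c(rows, dup = unname(rows["ref"]))
    profs$dup <- flat_profile("dup", 60, 0.9)
    tr3 <- conservation_track(ortholog_alignment(rows_dup, "ref"), profs)
    expect_true(all(tr3$seq_cons >= tr1$seq_cons - 1e-9))
  })
})

test_that("disorder classes follow the constrained/flexible definitions", {
  # ordered reference residues are ORDERED regardless of conservation
  rows <- setNames(rep(strrep("LVIF", 10), 4), c("ref", paste0("o", 1:3)))
  aln <- ortholog_alignment(rows, "ref")
  profs <- setNames(lapply(names(rows), function(rn) flat_profile(rn, 40, 0.1)),
                    names(rows))
  tr <- conservation_track(aln, profs)
  cls <- classify_disorder_conservation(tr, profs$ref)
  expect_equal(unique(cls), "ORDERED")

  # disorder conserved, sequence not -> FLEXIBLE
  withr::with_seed(71, {
    L <- 80
    rows <- c(ref = random_aa_seq(L, c("Q", "P", "E", "S")),
              setNames(vapply(1:9, function(i) random_aa_seq(L, c("Q", "P", "E", "S")),
                              character(1)), paste0("o", 1:9)))
  })
  profs <- setNames(lapply(names(rows), function(rn) flat_profile(rn, 80, 0.9)),
                    names(rows))
  tr <- conservation_track(ortholog_alignment(rows, "ref"), profs)
  cls <- classify_disorder_conservation(tr, profs$ref)
  expect_gte(mean(cls == "FLEXIBLE_DISORDER"), 0.95)
})

test_that("constrained percentage is monotone non-increasing in both thresholds", {
  withr::with_seed(73, {
    fam <- generate_family(family_config(seed = 73, n_proteins = 1))
    pid <- fam$proteins$id[1]
    aln <- generate_ortholog_alignment(fam, pid)
    profs <- setNames(lapply(names(aln$rows), function(rn) {
      predict_disorder_standin(gsub("-", "", aln$rows[[rn]], fixed = TRUE), rn)
    }), names(aln$rows))
    tr <- conservation_track(aln, profs)
    ref_prof <- profs[[pid]]
    L <- nchar(fam$proteins$sequence[1])
    reg <- regions(pid, 1, L, "CUSTOM")
    thr_grid <- c(0.2, 0.5, 0.75, 0.9, 0.99)
    for (fixed_dis in c(0.5, 0.75)) {
      pc <- vapply(thr_grid, function(st) {
        constrained_percent(
          classify_disorder_conservation(tr, ref_prof, fixed_dis, st), reg)
      }, numeric(1))
      expect_true(all(diff(pc) <= 1e-9))
    }
    for (fixed_seq in c(0.5, 0.9)) {
      pc <- vapply(thr_grid, function(dt) {
        constrained_percent(
          classify_disorder_conservation(tr, ref_prof, dt, fixed_seq), reg)
      }, numeric(1))
      expect_true(all(diff(pc) <= 1e-9))
    }
  })
})

test_that("constrained percentage counts region residues", {
  cls <- c(rep("CONSTRAINED_DISORDER", 5), rep("FLEXIBLE_DISORDER", 5))
  expect_equal(constrained_percent(cls, regions("p", 1, 5, "CUSTOM")), 100)
  expect_equal(constrained_percent(cls, regions("p", 1, 10, "CUSTOM")), 50)
})

test_that("clustal and aligned-FASTA inputs load to the same alignment", {
  rows <- c(seq1 = "MK-QP", seq2 = "MKAQP")
  fa <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">seq1", "MK-QP", ">seq2", "MKAQP"), fa)
  a1 <- read_alignment(fa)
  expect_equal(unname(a1$rows), unname(rows))
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "seq1            MK-QP", "seq2            MKAQP"), cl)
  a2 <- read_alignment(cl)
  expect_equal(toupper(unname(a2$rows)), unname(rows))
})
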