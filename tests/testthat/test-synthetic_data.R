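test_that("generation is deterministic and truth is internally consistent", {
  cfg <- family_config(seed = 5, n_proteins = 4)
  fam1 <- generate_family(cfg)
  fam2 <- generate_family(cfg)
  expect_identical(fam1, fam2)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(fam1$proteins, f1); write_fasta(fam2$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))

  # every planted motif matches its pattern at the recorded span
  hits <- fam1$truth$motif_hits
  cls <- fam1$truth$motif_classes
  for (r in seq_len(nrow(hits))) {
    s <- fam1$proteins$sequence[fam1$proteins$id == hits$protein_id[r]]
    sub <- substring(s, hits$start[r], hits$end[r])
    expect_identical(sub, hits$matched[r])
    pat <- cls$pattern[cls$id == hits$motif_id[r]]
    expect_true(grepl(paste0("^(?:", pat, ")$"), sub, perl = TRUE))
  }
  # planted features live inside their proteins and binding regions in IDRs
  validate_regions(fam1$truth$idr_regions, fam1$proteins)
  validate_regions(fam1$truth$binding_regions[, 1:5], fam1$proteins)
  for (r in seq_len(nrow(fam1$truth$binding_regions))) {
    b <- fam1$truth$binding_regions[r, ]
    host <- fam1$truth$idr_regions[fam1$truth$idr_regions$protein_id == b$protein_id, ]
    expect_true(any(host$start <= b$start & host$end >= b$end))
  }
  # variants sit inside their proteins
  lens <- setNames(nchar(fam1$proteins$sequence), fam1$proteins$id)
  expect_true(all(fam1$truth$variants$position >= 1))
  expect_true(all(fam1$truth$variants$position <=
                    lens[fam1$truth$variants$protein_id]))
})

test_that("infeasible plants are rejected before generation", {
  cfg <- family_config(seed = 1, n_proteins = 1,
                       architecture = data.frame(kind = c("ordered", "idr"),
                                                 length = c(100L, 30L)),
                       motif_plants = list(list(id = "m", pattern = "Q{40}",
                                                instance = strrep("Q", 40),
                                                tags = "", count = 1)))
  expect_error(generate_family(cfg), "longer than any IDR block")
  expect_error(family_config(binding_plants = list(list(length = 5,
                                                        conserved = TRUE,
                                                        count = 1))),
               ">= 8")
  cfg <- family_config(seed = 1, motif_plants = list(
    list(id = "m", pattern = "QQ", instance = "QK", tags = "", count = 1)))
  expect_error(generate_family(cfg), "does not match pattern")
})

test_that("oracle truth tracks let every segmentation stage recover the plants exactly", {
  fam <- generate_family(family_config(seed = 9, n_proteins = 3))
  dis <- generate_truth_tracks(fam, "disorder")
  for (pid in fam$proteins$id) {
    got <- segment_idrs(disorder_profile(dis[[pid]]))
    exp <- fam$truth$idr_regions[fam$truth$idr_regions$protein_id == pid, ]
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
  }
  bnd <- generate_truth_tracks(fam, "binding")
  for (pid in fam$proteins$id) {
    got <- candidate_binding_regions(binding_profile(bnd[[pid]]), min_len = 8)
    exp <- fam$truth$binding_regions[fam$truth$binding_regions$protein_id == pid, ]
    exp <- exp[order(exp$start), ]
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
  }
})

test_that("jittered truth tracks still recover planted IDRs nearly exactly", {
  fam <- generate_family(family_config(seed = 13, n_proteins = 3))
  dis <- generate_truth_tracks(fam, "disorder", jitter_sd = 0.05)
  for (pid in fam$proteins$id) {
    got <- segment_idrs(disorder_profile(dis[[pid]]))
    exp <- fam$truth$idr_regions[fam$truth$idr_regions$protein_id == pid, ]
    ov <- overlap_stats(got, exp)
    expect_gte(ov$jaccard, 0.95)
  }
})

test_that("ortholog alignments respect column classes and planted coordinates", {
  fam <- generate_family(family_config(seed = 17, n_proteins = 2))
  pid <- fam$proteins$id[1]

  # all-invariant: substitution probability 0 everywhere, no indels
  aln <- generate_ortholog_alignment(
    fam, pid, sub_prob = c(conserved = 0, ordered_bg = 0, idr_bg = 0),
    indel_prob = 0, insertion_prob = 0)
  expect_equal(length(unique(unname(aln$rows))), 1)
  expect_equal(aln$n_rows, 24)  # reference + 23 orthologs

  # substitution probability 1 with composition replacement: expected
  # match fraction to the reference is the self-coincidence of the
  # composition, far below the invariant case
  aln2 <- generate_ortholog_alignment(
    fam, pid, sub_prob = c(conserved = 0, ordered_bg = 1, idr_bg = 1),
    indel_prob = 0, insertion_prob = 0)
  ref <- strsplit(aln2$rows[[pid]], "")[[1]]
  cls <- fam$truth$column_classes[[pid]]
  bg <- which(cls != "conserved")
  match_frac <- mean(vapply(2:24, function(o) {
    mean(strsplit(aln2$rows[[o]], "")[[1]][bg] == ref[bg])
  }, numeric(1)))
  # expected coincidence: sum of squared composition frequencies ~ 0.07-0.1
  expect_lt(match_frac, 0.15)
  # conserved (planted) columns stay identical in every ortholog
  cons <- which(cls == "conserved")
  for (o in 2:24) {
    expect_true(all(strsplit(aln2$rows[[o]], "")[[1]][cons] == ref[cons]))
  }

  # indels never corrupt planted columns; reference stays ungapped-true
  aln3 <- generate_ortholog_alignment(fam, pid)
  refrow <- aln3$rows[[pid]]
  ungapped <- gsub("-", "", refrow, fixed = TRUE)
  expect_equal(ungapped, fam$proteins$sequence[1])
})

test_that("density-mode planting hits the requested per-1000-residue rate", {
  cfg <- family_config(seed = 21, n_proteins = 8,
                       motif_plants = list(list(id = "m", pattern = "QW.Q",
                                                instance = "QWAQ", tags = "PPI",
                                                density = 2)))
  fam <- generate_family(cfg)
  total <- sum(nchar(fam$proteins$sequence))
  planted <- nrow(fam$truth$motif_hits)
  # exact count recorded in truth; rate within rounding of the target
  expect_equal(planted, round(2 * 8 * sum(cfg$architecture$length) / 1000))
  expect_lt(abs(1000 * planted / total - 2), 0.5)
})
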