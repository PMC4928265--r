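# End-to-end orchestration: disorder -> LCR -> motif enrichment (+ null)
# -> conservation -> binding regions -> variant mapping, with a
# machine-readable JSON run report.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) with components:
#' \describe{
#'   \item{seed}{integer; mandatory whenever a stochastic stage (simulation
#'     or null ensemble) runs.}
#'   \item{simulate}{optional list of [family_config()] arguments — when
#'     present the input bundle is generated, otherwise `inputs` paths are
#'     read.}
#'   \item{inputs}{list with `fasta` and optionally `disorder_tracks`,
#'     `binding_tracks`, `motif_classes`, `variants`, `alignments` (a
#'     directory of `<protein_id>.afa` files).}
#'   \item{predictor}{`"standin"` (built-in predictors), `"truth"`
#'     (oracle tracks; simulated runs only) or `"external"` (score-track
#'     TSVs).}
#'   \item{thresholds}{`disorder` (0.5), `seq_cons` (0.9), `dis_cons`
#'     (0.75), `min_binding_len` (8), `min_conserved_run` (8),
#'     `jsd_window` (3), `idr_cutoff` (80), `alpha` (0.05).}
#'   \item{null}{`n_constructs` (20), `construct_length` (10000).}
#' }
#'
#' @param config list or YAML path.
#' @return normalized config list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    predictor = "standin",
    thresholds = list(disorder = 0.5, seq_cons = 0.9, dis_cons = 0.75,
                      min_binding_len = 8, min_conserved_run = 8,
                      jsd_window = 3, idr_cutoff = 80, alpha = 0.05),
    null = list(n_constructs = 20, construct_length = 10000),
    lcr = list(window = 12, entropy_trigger = 2.2, entropy_extend = 2.5,
               min_homorepeat = 5)
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        config[[nm]][[sub]] <- config[[nm]][[sub]] %||% defaults[[nm]][[sub]]
      }
    }
  }
  th <- config$thresholds
  stopifnot(th$disorder >= 0, th$disorder <= 1, th$seq_cons >= 0,
            th$seq_cons <= 1, th$min_binding_len >= 1, th$jsd_window >= 1,
            th$alpha > 0, th$alpha < 1)
  needs_seed <- !is.null(config$simulate) || !isFALSE(config$run_null %||% TRUE)
  if (needs_seed && is.null(config$seed)) {
    stop("config$seed is required when simulation or the null ensemble runs")
  }
  if (!config$predictor %in% c("standin", "truth", "external")) {
    stop("predictor must be 'standin', 'truth' or 'external'")
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes disorder profiling, IDR segmentation, LCR/homorepeat detection,
#' motif scanning with the shuffled null and enrichment test, per-protein
#' conservation (when alignments are available), two-step conserved
#' binding-region calling and variant mapping. Writes region BED/TSV
#' tables, a hits table and a sorted-key JSON report into `output_dir`.
#' Reruns with the same config produce an identical report.
#'
#' @param config see [pipeline_config()].
#' @param output_dir directory for outputs (created if missing).
#' @return the run report, invisibly (a named list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, output_dir = tempfile("idrpipe_run")) {
  config <- pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------
  family <- NULL
  alignments <- list()
  if (!is.null(config$simulate)) {
    family <- stage("simulate", {
      cfg <- do.call(family_config, c(list(seed = config$seed), config$simulate))
      generate_family(cfg)
    })
    proteins <- family$proteins
    classes <- family$truth$motif_classes
    variants <- family$truth$variants
    write_fasta(proteins, file.path(output_dir, "family.fasta"))
  } else {
    proteins <- stage("read_fasta", read_fasta(config$inputs$fasta))
    classes <- if (!is.null(config$inputs$motif_classes)) {
      stage("motif_classes", read_motif_classes(config$inputs$motif_classes))
    } else NULL
    variants <- if (!is.null(config$inputs$variants)) {
      stage("variants", read_variants(config$inputs$variants, proteins))
    } else NULL
    if (!is.null(config$inputs$alignments)) {
      for (pid in proteins$id) {
        f <- file.path(config$inputs$alignments, paste0(pid, ".afa"))
        if (file.exists(f)) alignments[[pid]] <- read_alignment(f, reference_id = pid)
      }
    }
  }

  # --- disorder profiles ---------------------------------------------
  profiles <- stage("disorder", {
    if (config$predictor == "truth") {
      if (is.null(family)) stop("'truth' predictor requires a simulated run")
      tr <- generate_truth_tracks(family, "disorder")
      lapply(tr, disorder_profile, threshold = th$disorder)
    } else if (config$predictor == "external") {
      tr <- read_score_tracks(config$inputs$disorder_tracks, proteins)
      lapply(tr, disorder_profile, threshold = th$disorder)
    } else {
      out <- lapply(seq_len(nrow(proteins)), function(k) {
        predict_disorder_standin(proteins$sequence[k], proteins$id[k],
                                 threshold = th$disorder)
      })
      setNames(out, proteins$id)
    }
  })
  summaries <- lapply(profiles, disorder_summary, cutoffs = th$idr_cutoff)
  idr <- do.call(rbind, lapply(profiles, segment_idrs))
  write_regions_bed(idr, file.path(output_dir, "idr.bed"))

  # --- LCR / homorepeats ---------------------------------------------
  lcr_par <- do.call(lcr_params, config$lcr)
  lcr_reg <- stage("lcr", do.call(rbind, lapply(seq_len(nrow(proteins)), function(k) {
    detect_lcr(proteins$sequence[k], proteins$id[k], lcr_par)
  })))
  rep_reg <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(k) {
    detect_homorepeats(proteins$sequence[k], proteins$id[k],
                       lcr_par$min_homorepeat)
  }))
  write_regions_bed(lcr_reg, file.path(output_dir, "lcr.bed"))
  lcr_idr_overlap <- overlap_stats(lcr_reg, idr)

  # --- motif enrichment ----------------------------------------------
  enrich <- NULL; hits <- NULL
  if (!is.null(classes) && nrow(classes) > 0) {
    hits <- stage("motifs", scan_motifs(proteins, classes, profiles,
                                        min_disorder_rate = th$disorder))
    scanned <- proteins$id[vapply(proteins$id, function(pid) {
      disorder_rate(profiles[[pid]]) > th$disorder
    }, logical(1))]
    n_res <- sum(nchar(proteins$sequence[proteins$id %in% scanned]))
    obs <- motif_density(hits, max(n_res, 1))
    if (!isFALSE(config$run_null %||% TRUE) && length(scanned) > 0) {
      pool <- disordered_residue_pool(proteins[proteins$id %in% scanned, ],
                                      profiles, th$disorder)
      nul <- stage("null", build_null(pool, config$null$n_constructs,
                                      config$null$construct_length,
                                      seed = derive_seed(config$seed, "null")))
      nd <- null_densities(nul, classes)
      per_protein <- vapply(scanned, function(pid) {
        1000 * sum(hits$protein_id == pid) / nchar(proteins$sequence[proteins$id == pid])
      }, numeric(1))
      enrich <- enrichment_test(unname(per_protein), nd, mode = "two_sample")
      enrich$observed_density <- obs$density_per_kaa
    }
    write.table(hits, file.path(output_dir, "motif_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # --- conservation + binding regions --------------------------------
  if (!is.null(family)) {
    alignments <- stage("alignments", {
      setNames(lapply(proteins$id, function(pid)
        generate_ortholog_alignment(family, pid)), proteins$id)
    })
  }
  binding_profiles <- stage("binding", {
    if (config$predictor == "truth") {
      tr <- generate_truth_tracks(family, "binding")
      lapply(tr, binding_profile, threshold = 0.5)
    } else if (config$predictor == "external" &&
               !is.null(config$inputs$binding_tracks)) {
      tr <- read_score_tracks(config$inputs$binding_tracks, proteins)
      lapply(tr, binding_profile, threshold = 0.5)
    } else {
      out <- lapply(seq_len(nrow(proteins)), function(k) {
        predict_binding_standin(proteins$sequence[k], profiles[[proteins$id[k]]],
                                proteins$id[k])
      })
      setNames(out, proteins$id)
    }
  })
  candidates <- do.call(rbind, lapply(binding_profiles, candidate_binding_regions,
                                      min_len = th$min_binding_len))
  conserved <- regions(); conserved$parent_start <- integer(0)
  conserved$parent_end <- integer(0)
  cons_summary <- list()
  for (pid in names(alignments)) {
    aln <- alignments[[pid]]
    row_profiles <- stage("conservation", {
      out <- lapply(names(aln$rows), function(rn) {
        ungapped <- gsub("-", "", aln$rows[[rn]], fixed = TRUE)
        if (rn == pid) profiles[[pid]]
        else predict_disorder_standin(ungapped, rn, threshold = th$disorder)
      })
      setNames(out, names(aln$rows))
    })
    track <- conservation_track(aln, row_profiles, window = th$jsd_window,
                                disorder_threshold = th$disorder)
    cls <- classify_disorder_conservation(track, profiles[[pid]],
                                          dis_thr = th$dis_cons,
                                          seq_thr = th$seq_cons)
    cons_summary[[pid]] <- table(factor(cls, levels = DISORDER_CONSERVATION_CLASSES))
    cand_p <- candidates[candidates$protein_id == pid, , drop = FALSE]
    conserved <- rbind(conserved,
                       conserved_binding_regions(cand_p, track,
                                                 seq_thr = th$seq_cons,
                                                 min_conserved_run = th$min_conserved_run))
  }
  write_regions_bed(candidates, file.path(output_dir, "binding_candidates.bed"))
  write_regions_bed(conserved[, c("protein_id", "start", "end", "kind", "score")],
                    file.path(output_dir, "conserved_binding.bed"))

  # --- variants -------------------------------------------------------
  var_map <- NULL
  target <- if (nrow(conserved) > 0) conserved else candidates
  if (!is.null(variants) && nrow(variants) > 0 && nrow(target) > 0) {
    var_map <- stage("variants", map_variants(target, variants))
    write.table(var_map$regions, file.path(output_dir, "regions_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- report ---------------------------------------------------------
  total_res <- sum(nchar(proteins$sequence))
  report <- list(
    binding = list(
      n_candidates = nrow(candidates),
      n_conserved = nrow(conserved),
      candidate_density_per_kaa = motif_density(nrow(candidates), total_res)$density_per_kaa
    ),
    conservation = lapply(cons_summary, function(tb) as.list(as.integer(tb))),
    disorder = list(
      mean_disorder_rate = mean(vapply(summaries, `[[`, numeric(1), "disorder_rate")),
      frac_idr_gt_cutoff = mean(vapply(summaries, function(s) any(s$has_idr_gt),
                                       logical(1))),
      idr_cutoff = th$idr_cutoff,
      n_idr_regions = nrow(idr)
    ),
    lcr = list(n_lcr = nrow(lcr_reg), n_homorepeats = nrow(rep_reg),
               idr_overlap_jaccard = lcr_idr_overlap$jaccard),
    motifs = if (!is.null(hits)) list(
      n_hits = nrow(hits),
      observed_density_per_kaa = if (!is.null(enrich)) enrich$observed_density else NA,
      null_mean_density_per_kaa = if (!is.null(enrich)) enrich$null_mean else NA,
      enrichment_p = if (!is.null(enrich)) enrich$p else NA,
      enrichment_t = if (!is.null(enrich)) enrich$t else NA
    ) else NULL,
    n_proteins = nrow(proteins),
    seed = config$seed,
    thresholds = th,
    variants = if (!is.null(var_map)) list(
      n_variants = if (!is.null(variants)) nrow(variants) else 0,
      n_mapped = nrow(var_map$assignments),
      n_unmapped = nrow(var_map$unmapped)
    ) else NULL
  )
  report <- report[order(names(report))]
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
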