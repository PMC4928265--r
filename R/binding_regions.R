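# Disordered binding-region calling (two-step: candidates >= 8 residues,
# then conservation intersection at >= 0.9) and variant-to-region mapping.

#' Built-in binding-propensity predictor
#'
#' A documented heuristic standing in for an external disordered-binding
#' predictor: the per-residue binding propensity is a logistic of the
#' windowed interface-residue enrichment (centered moving average of
#' [interface_propensity], window 9) multiplied by the residue's disorder
#' score — segments must be both disordered and enriched in
#' interaction-prone residues to score high. External binding tracks (e.g.
#' real ANCHOR output) can be supplied instead via [read_score_tracks()] +
#' [binding_profile()].
#'
#' @param sequence amino-acid sequence.
#' @param disorder the protein's [disorder_profile()] (or numeric score
#'   vector in `[0, 1]`).
#' @param protein_id identifier recorded on the output track.
#' @param scale interface propensity scale, default [interface_propensity].
#' @param window odd smoothing window, default 9.
#' @param midpoint,slope logistic parameters, defaults 0.05 and 8.
#' @param threshold binding threshold stored on the profile, default 0.5.
#' @return a `binding_profile` (same structure as [disorder_profile()]).
#' @export
predict_binding_standin <- function(sequence, disorder, protein_id = "protein",
                                    scale = interface_propensity, window = 9,
                                    midpoint = 0.05, slope = 8,
                                    threshold = 0.5) {
  s <- check_aa_sequence(sequence, protein_id)
  ch <- seq_chars(s)
  dvals <- if (inherits(disorder, "disorder_profile")) disorder$track$values else disorder
  if (length(dvals) != length(ch)) stop("disorder values must match sequence length")
  vals <- unname(scale[ch])
  vals[ch == "X"] <- 0
  enrich <- moving_average(vals, window)
  score <- logistic(slope * (enrich * dvals - midpoint))
  binding_profile(score_track(protein_id, score, source = "standin"),
                  threshold = threshold)
}

#' @rdname predict_binding_standin
#' @param track a [score_track()] with values in `[0, 1]`.
#' @export
binding_profile <- function(track, threshold = 0.5) {
  stopifnot(inherits(track, "score_track"))
  if (any(track$values < 0 | track$values > 1)) {
    stop("binding profile values must lie in [0, 1]")
  }
  structure(list(track = track, threshold = threshold),
            class = c("binding_profile", "disorder_profile"))
}

#' Candidate disordered binding regions
#'
#' Maximal runs of residues with binding score at or above the profile
#' threshold, kept when at least `min_len` residues long (default 8).
#'
#' @param profile a [binding_profile()].
#' @param min_len minimum region length, default 8.
#' @return region table of kind `BINDING_CANDIDATE`; `score` is the mean
#'   binding score.
#' @export
candidate_binding_regions <- function(profile, min_len = 8) {
  stopifnot(min_len >= 1)
  v <- profile$track$values
  r <- runs_from_mask(v >= profile$threshold, min_len = min_len)
  if (nrow(r) == 0) return(regions())
  sc <- vapply(seq_len(nrow(r)),
               function(i) mean(v[r$start[i]:r$end[i]]), numeric(1))
  regions(profile$track$protein_id, r$start, r$end, "BINDING_CANDIDATE", sc)
}

#' Conserved disordered binding regions
#'
#' Second step of the two-step procedure: intersects candidate binding
#' regions with the sequence-conservation track. In `"residue"` mode (the
#' default) each candidate is reduced to its maximal sub-runs of residues
#' with `seq_cons >= seq_thr`, and sub-runs shorter than
#' `min_conserved_run` are dropped; in `"whole_region"` mode a candidate is
#' kept in full when its mean `seq_cons` reaches `seq_thr`.
#'
#' @param candidates region table of kind `BINDING_CANDIDATE` (one protein).
#' @param track the protein's [conservation_track()].
#' @param seq_thr conservation threshold, default 0.9.
#' @param min_conserved_run minimum surviving run length, default 8.
#' @param mode `"residue"` or `"whole_region"`.
#' @return region table of kind `CONSERVED_BINDING` with extra columns
#'   `parent_start`, `parent_end`; sorted and disjoint. `score` is the mean
#'   `seq_cons`.
#' @export
conserved_binding_regions <- function(candidates, track, seq_thr = 0.9,
                                      min_conserved_run = 8,
                                      mode = c("residue", "whole_region")) {
  mode <- match.arg(mode)
  if (nrow(candidates) == 0) {
    out <- regions(); out$parent_start <- integer(0); out$parent_end <- integer(0)
    return(out)
  }
  cons <- rep(NA_real_, max(track$residue, candidates$end))
  cons[track$residue] <- track$seq_cons
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    span <- candidates$start[i]:candidates$end[i]
    if (anyNA(cons[span])) {
      stop(sprintf("candidate [%d, %d] outside conservation track coverage",
                   candidates$start[i], candidates$end[i]))
    }
    if (mode == "whole_region") {
      if (mean(cons[span]) >= seq_thr) {
        r <- data.frame(start = candidates$start[i], end = candidates$end[i])
      } else {
        r <- data.frame(start = integer(0), end = integer(0))
      }
    } else {
      r <- runs_from_mask(cons[span] >= seq_thr, min_len = min_conserved_run)
      if (nrow(r) > 0) {
        r$start <- r$start + candidates$start[i] - 1L
        r$end <- r$end + candidates$start[i] - 1L
      }
    }
    if (nrow(r) == 0) next
    reg <- regions(candidates$protein_id[i], r$start, r$end, "CONSERVED_BINDING",
                   vapply(seq_len(nrow(r)),
                          function(k) mean(cons[r$start[k]:r$end[k]]), numeric(1)))
    reg$parent_start <- candidates$start[i]
    reg$parent_end <- candidates$end[i]
    out[[length(out) + 1]] <- reg
  }
  if (length(out) == 0) {
    out <- regions(); out$parent_start <- integer(0); out$parent_end <- integer(0)
    return(out)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id, res$start), ]
  rownames(res) <- NULL
  res
}

#' Map variants onto regions
#'
#' A variant maps to a region when `start <= position <= end` on the same
#' protein; a variant can map to several overlapping regions.
#'
#' @param reg region table.
#' @param variants data.frame with columns `protein_id`, `position` (and
#'   optionally `annotation`).
#' @return list with `regions` (the input regions plus an `n_variants`
#'   column), `assignments` (one row per variant-region pair) and
#'   `unmapped` (variants hitting no region).
#' @export
map_variants <- function(reg, variants) {
  n_var <- integer(nrow(reg))
  hit_any <- logical(nrow(variants))
  assign_rows <- list()
  for (i in seq_len(nrow(reg))) {
    in_reg <- variants$protein_id == reg$protein_id[i] &
      variants$position >= reg$start[i] & variants$position <= reg$end[i]
    n_var[i] <- sum(in_reg)
    hit_any <- hit_any | in_reg
    if (any(in_reg)) {
      assign_rows[[length(assign_rows) + 1]] <- data.frame(
        region_row = i, protein_id = reg$protein_id[i],
        start = reg$start[i], end = reg$end[i],
        position = variants$position[in_reg],
        annotation = variants$annotation[in_reg] %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  reg$n_variants <- n_var
  list(regions = reg,
       assignments = if (length(assign_rows) > 0) do.call(rbind, assign_rows)
                     else data.frame(region_row = integer(0),
                                     protein_id = character(0),
                                     start = integer(0), end = integer(0),
                                     position = integer(0),
                                     annotation = character(0)),
       unmapped = variants[!hit_any, , drop = FALSE])
}

#' Interval overlap between two regions
#'
#' @param region_a,region_b one-row region tables on the same protein.
#' @return list with `overlaps` (logical) and `shared_residues`
#'   (`max(0, min(end_a, end_b) - max(start_a, start_b) + 1)`).
#' @export
region_overlap <- function(region_a, region_b) {
  stopifnot(nrow(region_a) == 1, nrow(region_b) == 1)
  if (region_a$protein_id != region_b$protein_id) {
    stop("regions lie on different proteins")
  }
  shared <- max(0L, min(region_a$end, region_b$end) -
                  max(region_a$start, region_b$start) + 1L)
  list(overlaps = shared > 0, shared_residues = as.integer(shared))
}
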