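# Disorder profiling, IDR segmentation and family-level summaries.

#' Construct a disorder profile
#'
#' Wraps a per-residue [score_track()] with values in `[0, 1]` together with
#' the classification threshold. The disorder rate of a protein is the
#' fraction of residues scoring at or above the threshold (default 0.5).
#'
#' @param track a [score_track()] with values in `[0, 1]`.
#' @param threshold disorder classification threshold.
#' @return list of class `disorder_profile`.
#' @export
disorder_profile <- function(track, threshold = 0.5) {
  stopifnot(inherits(track, "score_track"))
  if (any(track$values < 0 | track$values > 1)) {
    stop("disorder profile values must lie in [0, 1]")
  }
  structure(list(track = track, threshold = threshold),
            class = "disorder_profile")
}

#' Built-in composition-scale disorder predictor
#'
#' A documented stand-in for an external disorder predictor: per-residue
#' propensity is the centered moving average (window truncated at the
#' termini) of a residue scale, mapped through a logistic to `[0, 1]`.
#' Deterministic. External per-residue tracks (e.g. real IUPred output)
#' can be supplied instead via [read_score_tracks()] + [disorder_profile()].
#'
#' @param sequence amino-acid sequence (X allowed; scored at the midpoint,
#'   i.e. neutrally).
#' @param protein_id identifier recorded on the output track.
#' @param scale named numeric vector mapping each standard residue to a
#'   disorder propensity; default [disorder_propensity] (TOP-IDP).
#' @param window odd smoothing window (residues), default 21.
#' @param midpoint logistic midpoint on the scale's axis; default the mean of
#'   `scale` (so an average-composition window scores 0.5).
#' @param slope logistic steepness, default 4.
#' @param threshold disorder threshold stored on the profile, default 0.5.
#' @return a [disorder_profile()].
#' @export
predict_disorder_standin <- function(sequence, protein_id = "protein",
                                     scale = disorder_propensity,
                                     window = 21, midpoint = NULL, slope = 4,
                                     threshold = 0.5) {
  stopifnot(window >= 1, window %% 2 == 1)
  s <- check_aa_sequence(sequence, protein_id)
  ch <- seq_chars(s)
  if (is.null(midpoint)) midpoint <- mean(scale)
  missing_res <- setdiff(unique(ch), c(names(scale), "X"))
  if (length(missing_res) > 0) {
    stop(sprintf("residue(s) absent from scale table: %s",
                 paste(missing_res, collapse = ", ")))
  }
  vals <- unname(scale[ch])
  vals[ch == "X"] <- midpoint
  smoothed <- moving_average(vals, window)
  score <- logistic(slope * (smoothed - midpoint))
  disorder_profile(score_track(protein_id, score, source = "standin"),
                   threshold = threshold)
}

#' Disorder rate of a profile
#'
#' Fraction of residues with disorder score at or above the profile
#' threshold.
#'
#' @param profile a [disorder_profile()].
#' @return numeric in `[0, 1]`.
#' @export
disorder_rate <- function(profile) {
  mean(profile$track$values >= profile$threshold)
}

#' Segment intrinsically disordered regions
#'
#' Maximal runs of consecutive residues with disorder score at or above the
#' profile threshold. No merging across sub-threshold residues.
#'
#' @param profile a [disorder_profile()].
#' @return region table of kind `IDR` (possibly empty), sorted and disjoint;
#'   `score` is the mean disorder score of the region.
#' @export
segment_idrs <- function(profile) {
  v <- profile$track$values
  r <- runs_from_mask(v >= profile$threshold)
  if (nrow(r) == 0) return(regions())
  sc <- vapply(seq_len(nrow(r)),
               function(i) mean(v[r$start[i]:r$end[i]]), numeric(1))
  regions(profile$track$protein_id, r$start, r$end, "IDR", sc)
}

#' Per-protein disorder summary
#'
#' @param profile a [disorder_profile()].
#' @param cutoffs IDR length cutoffs for the `has_idr_gt` flags; an IDR
#'   "longer than" a cutoff means strictly greater.
#' @return list with `protein_id`, `disorder_rate`, `idr_regions`,
#'   `longest_idr` and named logical `has_idr_gt`.
#' @export
disorder_summary <- function(profile, cutoffs = 80) {
  idr <- segment_idrs(profile)
  longest <- if (nrow(idr) == 0) 0L else max(idr$end - idr$start + 1L)
  list(protein_id = profile$track$protein_id,
       disorder_rate = disorder_rate(profile),
       idr_regions = idr,
       longest_idr = longest,
       has_idr_gt = setNames(longest > cutoffs, paste0("gt", cutoffs)))
}

#' Family-level disorder table
#'
#' Aggregates per-protein summaries by family: mean disorder rate, fraction
#' of proteins carrying at least one IDR strictly longer than each cutoff,
#' and family size.
#'
#' @param summaries list of [disorder_summary()] results.
#' @param proteins a [protein_set()] supplying the `family` labels.
#' @param cutoffs length cutoffs (strictly-greater), default 80.
#' @return data.frame, one row per family with >= 1 summarized protein;
#'   families present in `proteins` but absent from `summaries` are dropped
#'   with a warning.
#' @export
family_disorder_table <- function(summaries, proteins, cutoffs = 80) {
  ids <- vapply(summaries, `[[`, character(1), "protein_id")
  fam <- setNames(proteins$family, proteins$id)[ids]
  empty <- setdiff(unique(proteins$family[!is.na(proteins$family)]),
                   unique(fam))
  if (length(empty) > 0) {
    warning(sprintf("family with no summarized proteins excluded: %s",
                    paste(empty, collapse = ", ")))
  }
  rows <- lapply(split(seq_along(summaries), fam), function(ix) {
    sub <- summaries[ix]
    row <- data.frame(
      family = fam[ix[1]],
      n = length(sub),
      mean_disorder_rate = mean(vapply(sub, `[[`, numeric(1), "disorder_rate")),
      stringsAsFactors = FALSE
    )
    for (co in cutoffs) {
      longest <- vapply(sub, `[[`, numeric(1), "longest_idr")
      row[[paste0("frac_idr_gt", co)]] <- mean(longest > co)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise family length comparisons within taxon groups
#'
#' For each group, runs two-sample t-tests of mean protein length between
#' every pair of families (Welch by default; pooled variance via
#' `var_equal = TRUE`). Cells with fewer than 2 observations are reported as
#' untestable rather than dropped. Zero-variance degenerate pairs are
#' reported with `t = Inf` (or 0 when the means agree) and a note.
#'
#' @param length_table data.frame with columns `family`, `group`, `length`.
#' @param alpha significance threshold, default 0.05.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param bonferroni also report Bonferroni-adjusted p values (the raw p is
#'   always kept).
#' @return data.frame with one row per (group, family pair): group, family_a,
#'   family_b, mean/sd/n per side, t, df, p, significant, note.
#' @export
compare_groups <- function(length_table, alpha = 0.05, var_equal = FALSE,
                           bonferroni = FALSE) {
  stopifnot(all(c("family", "group", "length") %in% names(length_table)))
  out <- list()
  for (grp in unique(length_table$group)) {
    sub <- length_table[length_table$group == grp, ]
    fams <- sort(unique(sub$family))
    if (length(fams) < 2) next
    for (i in seq_len(length(fams) - 1)) {
      for (j in seq(i + 1, length(fams))) {
        xa <- sub$length[sub$family == fams[i]]
        xb <- sub$length[sub$family == fams[j]]
        row <- data.frame(group = grp, family_a = fams[i], family_b = fams[j],
                          mean_a = mean(xa), sd_a = sd(xa), n_a = length(xa),
                          mean_b = mean(xb), sd_b = sd(xb), n_b = length(xb),
                          t = NA_real_, df = NA_real_, p = NA_real_,
                          significant = NA, note = "",
                          stringsAsFactors = FALSE)
        if (length(xa) < 2 || length(xb) < 2) {
          row$note <- "untestable: n < 2"
        } else if (sd(xa) == 0 && sd(xb) == 0) {
          # degenerate: both samples constant
          if (mean(xa) == mean(xb)) {
            row$t <- 0; row$p <- 1
            row$note <- "zero variance, equal means"
          } else {
            row$t <- Inf; row$p <- 1e-15
            row$note <- "zero variance, means differ; p < 1e-12"
          }
          row$significant <- row$p < alpha
        } else {
          tt <- t.test(xa, xb, var.equal = var_equal)
          row$t <- unname(tt$statistic)
          row$df <- unname(tt$parameter)
          row$p <- tt$p.value
          row$significant <- tt$p.value < alpha
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  if (bonferroni) {
    res$p_bonferroni <- p.adjust(res$p, method = "bonferroni")
    res$significant_bonferroni <- res$p_bonferroni < alpha
  }
  rownames(res) <- NULL
  res
}
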