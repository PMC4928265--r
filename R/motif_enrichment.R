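# Linear-motif scanning of mostly disordered proteins, the shuffled-sequence
# null ensemble, density statistics and enrichment tests.

# All match occurrences of one pattern in one string, overlapping starts
# included, via a zero-width lookahead wrapper.
scan_pattern <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=(", pattern, "))"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  starts <- as.integer(m)
  lens <- attr(m, "capture.length")[, 1]
  keep <- lens > 0
  data.frame(start = starts[keep], end = starts[keep] + lens[keep] - 1L)
}

#' Scan disordered proteins for linear-motif classes
#'
#' Only proteins whose disorder rate exceeds `min_disorder_rate` (default
#' 0.5, i.e. "mostly disordered") are scanned. All match occurrences are
#' reported, including overlapping matches at distinct start positions.
#' Optionally, individual hits can additionally be required to lie in
#' disordered sequence: a hit is kept when at least
#' `require_disordered_fraction` of its residues score at or above the
#' disorder threshold (default 0 keeps all hits — the filter applies to
#' proteins, not hits).
#'
#' @param proteins a [protein_set()].
#' @param classes a [motif_classes()] table.
#' @param profiles named list of [disorder_profile()], one per protein.
#' @param min_disorder_rate whole-protein disorder-rate filter (strict),
#'   default 0.5.
#' @param require_disordered_fraction per-hit disordered-residue fraction,
#'   default 0.
#' @return data.frame of hits (motif_id, protein_id, start, end, matched),
#'   ordered by protein (input order), start, motif_id.
#' @export
scan_motifs <- function(proteins, classes, profiles,
                        min_disorder_rate = 0.5,
                        require_disordered_fraction = 0) {
  stopifnot(require_disordered_fraction >= 0, require_disordered_fraction <= 1)
  missing_prof <- setdiff(proteins$id, names(profiles))
  if (length(missing_prof) > 0) {
    stop(sprintf("no disorder profile for protein(s): %s",
                 paste(missing_prof, collapse = ", ")))
  }
  out <- list()
  for (k in seq_len(nrow(proteins))) {
    pid <- proteins$id[k]
    prof <- profiles[[pid]]
    if (disorder_rate(prof) <= min_disorder_rate) next
    dis <- prof$track$values >= prof$threshold
    for (ci in seq_len(nrow(classes))) {
      hits <- scan_pattern(proteins$sequence[k], classes$pattern[ci])
      if (nrow(hits) == 0) next
      if (require_disordered_fraction > 0) {
        frac <- vapply(seq_len(nrow(hits)), function(i) {
          mean(dis[hits$start[i]:hits$end[i]])
        }, numeric(1))
        hits <- hits[frac >= require_disordered_fraction, , drop = FALSE]
      }
      if (nrow(hits) == 0) next
      out[[length(out) + 1]] <- data.frame(
        motif_id = classes$id[ci], protein_id = pid,
        start = hits$start, end = hits$end,
        matched = substring(proteins$sequence[k], hits$start, hits$end),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif_id = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      matched = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$protein_id, proteins$id), res$start, res$motif_id), ]
  rownames(res) <- NULL
  res
}

#' Pool the disordered residues of a protein set
#'
#' Concatenates, across proteins, the residues whose disorder score is at or
#' above `threshold`. `X` residues are excluded (with a message recording the
#' count), since they carry no compositional information.
#'
#' @param proteins a [protein_set()].
#' @param profiles named list of [disorder_profile()].
#' @param threshold disorder threshold, default 0.5.
#' @return character vector of residues.
#' @export
disordered_residue_pool <- function(proteins, profiles, threshold = 0.5) {
  pool <- character(0)
  for (k in seq_len(nrow(proteins))) {
    pid <- proteins$id[k]
    prof <- profiles[[pid]]
    if (is.null(prof)) stop(sprintf("no disorder profile for '%s'", pid))
    ch <- seq_chars(proteins$sequence[k])
    pool <- c(pool, ch[prof$track$values >= threshold])
  }
  nx <- sum(pool == "X")
  if (nx > 0) message(sprintf("excluding %d X residue(s) from pool", nx))
  pool[pool != "X"]
}

#' Build the shuffled-sequence null ensemble
#'
#' Emulates the randomized-sequence control: synthetic constructs with the
#' amino-acid composition of a pool of disordered residues. Two modes:
#' `"permute"` is an exact shuffle of the pool (requires the total construct
#' length to equal the pool size; conserves the residue multiset exactly);
#' `"resample"` draws residues i.i.d. from the pool composition, which is
#' what a coverage above 1x (e.g. the default 20 constructs of 10,000
#' residues over a ~20,000-residue pool, a 10x coverage) requires. `"auto"`
#' picks permute on exact size match, resample otherwise.
#'
#' @param pool character vector of residues (see
#'   [disordered_residue_pool()]).
#' @param n_constructs number of constructs, default 20.
#' @param construct_length residues per construct, default 10000.
#' @param seed integer seed; the ensemble is bit-identical across runs for a
#'   fixed seed.
#' @param mode `"auto"`, `"resample"` or `"permute"`.
#' @return list of class `null_ensemble` with fields `constructs` (character
#'   vector of sequences), `n_constructs`, `construct_length`,
#'   `source_composition` (residue count table of the pool), `seed`, `mode`.
#' @export
build_null <- function(pool, n_constructs = 20, construct_length = 10000,
                       seed, mode = c("auto", "resample", "permute")) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required for the null ensemble")
  stopifnot(n_constructs >= 1, construct_length >= 1, length(pool) > 0)
  pool <- pool[pool != "X"]
  if (length(pool) < 20) {
    warning("pool smaller than 20 residues; composition estimate unstable")
  }
  total <- n_constructs * construct_length
  if (mode == "auto") {
    mode <- if (total == length(pool)) "permute" else "resample"
  }
  comp <- table(factor(pool, levels = AA_ALPHABET))
  res <- withr::with_seed(seed, {
    if (mode == "permute") {
      if (total != length(pool)) {
        stop("permute mode requires n_constructs * construct_length == pool size")
      }
      shuffled <- sample(pool)
      split(shuffled, rep(seq_len(n_constructs), each = construct_length))
    } else {
      draws <- sample(AA_ALPHABET, total, replace = TRUE,
                      prob = as.numeric(comp) / sum(comp))
      split(draws, rep(seq_len(n_constructs), each = construct_length))
    }
  })
  constructs <- vapply(res, paste, character(1), collapse = "")
  structure(list(constructs = unname(constructs),
                 n_constructs = as.integer(n_constructs),
                 construct_length = as.integer(construct_length),
                 source_composition = comp, seed = seed, mode = mode),
            class = "null_ensemble")
}

#' Motif density per 1000 residues
#'
#' @param n_hits number of motif hits (or a hit data.frame, whose rows are
#'   counted).
#' @param n_residues number of residues scanned (>= 1).
#' @return list of class `density_stat` with `n_hits`, `n_residues`,
#'   `density_per_kaa` (= 1000 * n_hits / n_residues).
#' @export
motif_density <- function(n_hits, n_residues) {
  if (is.data.frame(n_hits)) n_hits <- nrow(n_hits)
  if (n_residues < 1) stop("n_residues must be >= 1")
  structure(list(n_hits = as.integer(n_hits),
                 n_residues = as.integer(n_residues),
                 density_per_kaa = 1000 * n_hits / n_residues),
            class = "density_stat")
}

#' Per-construct motif densities of a null ensemble
#'
#' Scans every construct with every motif class and returns the total hit
#' density (per 1000 residues) of each construct.
#'
#' @param ensemble a [build_null()] ensemble.
#' @param classes a [motif_classes()] table.
#' @return numeric vector of length `n_constructs`.
#' @export
null_densities <- function(ensemble, classes) {
  vapply(ensemble$constructs, function(s) {
    hits <- sum(vapply(classes$pattern,
                       function(p) nrow(scan_pattern(s, p)), numeric(1)))
    1000 * hits / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Motif enrichment test against the null ensemble
#'
#' `one_sample` runs a one-sample t-test of the per-construct null densities
#' against the observed density (a single number); `two_sample` runs a
#' Welch two-sample t-test of per-protein observed densities against the
#' per-construct null densities. An empirical p value,
#' `(1 + #\{null >= observed\}) / (1 + #null)`, is always reported
#' alongside (for `two_sample` the observed value is the mean of the
#' per-protein densities). If the null densities are constant the t-test is
#' undefined; the empirical p is returned with a warning.
#'
#' @param observed observed density (scalar for `one_sample`, vector of
#'   per-protein densities for `two_sample`).
#' @param null_densities numeric vector of per-construct densities (>= 2 for
#'   the t-based modes).
#' @param mode `"one_sample"` or `"two_sample"`.
#' @return list with `t`, `df`, `p`, `empirical_p`, `observed_mean`,
#'   `null_mean`, `mode`.
#' @export
enrichment_test <- function(observed, null_densities,
                            mode = c("one_sample", "two_sample")) {
  mode <- match.arg(mode)
  if (length(null_densities) < 2) stop("need >= 2 null densities")
  obs_point <- mean(observed)
  emp <- (1 + sum(null_densities >= obs_point)) / (1 + length(null_densities))
  t_val <- df_val <- p_val <- NA_real_
  if (sd(null_densities) == 0 &&
      (mode == "one_sample" || sd(observed) == 0 || length(observed) < 2)) {
    warning("constant null densities; reporting empirical p only")
  } else if (mode == "one_sample") {
    if (length(observed) != 1) stop("one_sample mode needs a scalar observed density")
    tt <- t.test(null_densities, mu = observed)
    t_val <- unname(tt$statistic); df_val <- unname(tt$parameter)
    p_val <- tt$p.value
  } else {
    if (length(observed) < 2) stop("two_sample mode needs >= 2 per-protein densities")
    tt <- t.test(observed, null_densities)
    t_val <- unname(tt$statistic); df_val <- unname(tt$parameter)
    p_val <- tt$p.value
  }
  list(t = t_val, df = df_val, p = p_val, empirical_p = emp,
       observed_mean = obs_point, null_mean = mean(null_densities),
       mode = mode)
}

#' Filter motif classes or hits by functional tag
#'
#' For a [motif_classes()] table, keeps the classes carrying `tag` in their
#' comma-separated tag list; for a hit table, keeps the hits whose motif
#' class carries the tag (`classes` must then be supplied). An unknown tag
#' yields an empty subset with a warning.
#'
#' @param x a motif class table or a hit data.frame.
#' @param tag tag to filter by (e.g. `"PPI"`).
#' @param classes the class table, required when `x` is a hit table.
#' @return subset of `x`.
#' @export
filter_by_tag <- function(x, tag, classes = NULL) {
  stopifnot(nzchar(tag))
  if (!is.null(x$pattern)) {
    cls <- x
  } else {
    if (is.null(classes)) stop("filtering hits by tag requires the class table")
    cls <- classes
  }
  tag_list <- strsplit(cls$tags, ",\\s*")
  has <- vapply(tag_list, function(tl) tag %in% tl, logical(1))
  if (!any(has)) warning(sprintf("no motif class carries tag '%s'", tag))
  if (!is.null(x$pattern)) {
    x[has, , drop = FALSE]
  } else {
    x[x$motif_id %in% cls$id[has], , drop = FALSE]
  }
}
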