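# Low-complexity and homorepeat detection by windowed Shannon entropy,
# in the style of SEG's trigger/extend scheme.

#' Low-complexity detection parameters
#'
#' `entropy_trigger`/`entropy_extend` are in bits; the defaults (2.2 / 2.5
#' at window 12) mirror the conventional SEG parameter set expressed in
#' bits.
#'
#' @param window window length in residues (>= 2), default 12.
#' @param entropy_trigger seed threshold in bits, default 2.2.
#' @param entropy_extend extension threshold in bits (>= trigger), default 2.5.
#' @param min_homorepeat minimum single-residue run length, default 5.
#' @return list of class `lcr_params`.
#' @export
lcr_params <- function(window = 12, entropy_trigger = 2.2,
                       entropy_extend = 2.5, min_homorepeat = 5) {
  stopifnot(window >= 2, entropy_trigger <= entropy_extend,
            min_homorepeat >= 2)
  structure(list(window = as.integer(window),
                 entropy_trigger = entropy_trigger,
                 entropy_extend = entropy_extend,
                 min_homorepeat = as.integer(min_homorepeat)),
            class = "lcr_params")
}

#' Shannon entropy of a residue window
#'
#' \eqn{H = -\sum_a f_a \log_2 f_a} over the residue frequencies of the
#' window. `X` residues are excluded before computing frequencies.
#'
#' @param window_seq a character string (or character vector of residues).
#' @return entropy in bits, in `[0, log2(min(n, 20))]`.
#' @export
window_entropy <- function(window_seq) {
  ch <- if (length(window_seq) == 1) seq_chars(window_seq) else window_seq
  ch <- ch[ch != "X"]
  if (length(ch) == 0) stop("empty window (or all-X window)")
  f <- tabulate(factor(ch, levels = AA_ALPHABET), nbins = 20)
  f <- f[f > 0] / sum(f)
  -sum(f * log2(f))
}

# Entropy of every window of length w; returns vector of length n - w + 1.
sliding_entropy <- function(ch, w) {
  n <- length(ch)
  counts <- integer(20)
  idx <- match(ch, AA_ALPHABET)  # NA for X
  out <- numeric(n - w + 1)
  inwin <- idx[1:w]
  for (a in inwin[!is.na(inwin)]) counts[a] <- counts[a] + 1L
  ent <- function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) return(NA_real_)
    f <- cnt[cnt > 0] / tot
    -sum(f * log2(f))
  }
  out[1] <- ent(counts)
  if (n - w >= 1) {
    for (i in seq_len(n - w)) {
      old <- idx[i]; new <- idx[i + w]
      if (!is.na(old)) counts[old] <- counts[old] - 1L
      if (!is.na(new)) counts[new] <- counts[new] + 1L
      out[i + 1] <- ent(counts)
    }
  }
  out
}

#' Detect low-complexity regions
#'
#' SEG-style two-threshold scheme: windows with entropy at or below the
#' trigger seed a region; the seed is extended over contiguous neighbouring
#' windows whose entropy stays at or below the extend threshold; the
#' residue span of all included windows is reported and overlapping regions
#' are merged.
#'
#' @param sequence amino-acid sequence.
#' @param protein_id identifier for the output regions.
#' @param params an [lcr_params()].
#' @return region table of kind `LCR`; `score` is the minimum window entropy
#'   inside the region.
#' @export
detect_lcr <- function(sequence, protein_id = "protein", params = lcr_params()) {
  s <- check_aa_sequence(sequence, protein_id)
  ch <- seq_chars(s)
  w <- params$window
  if (length(ch) < w) {
    stop(sprintf("sequence shorter than window (%d < %d)", length(ch), w))
  }
  H <- sliding_entropy(ch, w)
  ext <- !is.na(H) & H <= params$entropy_extend
  trig <- !is.na(H) & H <= params$entropy_trigger
  blocks <- runs_from_mask(ext)  # window-index space
  out <- regions()
  for (i in seq_len(nrow(blocks))) {
    wi <- blocks$start[i]:blocks$end[i]
    if (!any(trig[wi])) next
    out <- rbind(out, regions(protein_id, wi[1], wi[length(wi)] + w - 1L,
                              "LCR", NA_real_))
  }
  if (nrow(out) == 0) return(regions())
  out <- merge_overlapping(out)
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    wi <- out$start[i]:(out$end[i] - w + 1L)
    min(H[wi], na.rm = TRUE)
  }, numeric(1))
  out
}

# Merge overlapping/adjacent-overlap regions of one protein+kind.
merge_overlapping <- function(reg) {
  if (nrow(reg) <= 1) return(reg)
  reg <- reg[order(reg$protein_id, reg$start, reg$end), ]
  out <- reg[1, ]
  for (i in seq(2, nrow(reg))) {
    last <- nrow(out)
    if (reg$protein_id[i] == out$protein_id[last] &&
        reg$start[i] <= out$end[last] + 0L) {
      out$end[last] <- max(out$end[last], reg$end[i])
    } else {
      out <- rbind(out, reg[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect single-residue homorepeats
#'
#' Maximal runs of one residue with length at least `min_len` (e.g. polyQ
#' stretches).
#'
#' @param sequence amino-acid sequence.
#' @param protein_id identifier for the output regions.
#' @param min_len minimum run length, default 5.
#' @return region table of kind `HOMOREPEAT` with `score` = run length and
#'   an extra `residue` column.
#' @export
detect_homorepeats <- function(sequence, protein_id = "protein", min_len = 5) {
  stopifnot(min_len >= 2)
  ch <- seq_chars(check_aa_sequence(sequence, protein_id))
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values != "X"
  out <- regions(protein_id, starts[keep], ends[keep], "HOMOREPEAT",
                 as.numeric(r$lengths[keep]))
  out$residue <- r$values[keep]
  out
}

#' Residue-set overlap statistics between two region sets
#'
#' Computes the Jaccard index of the residue sets covered by the two region
#' tables and the directional coverage fractions, over the union of proteins
#' they mention.
#'
#' @param regions_a,regions_b region tables.
#' @return list with `jaccard`, `frac_a_in_b`, `frac_b_in_a` (NA components
#'   where a set is empty).
#' @export
overlap_stats <- function(regions_a, regions_b) {
  pids <- union(unique(regions_a$protein_id), unique(regions_b$protein_id))
  n_a <- 0; n_b <- 0; n_ab <- 0
  for (pid in pids) {
    ra <- regions_a[regions_a$protein_id == pid, ]
    rb <- regions_b[regions_b$protein_id == pid, ]
    L <- max(0L, ra$end, rb$end)
    ma <- logical(L); mb <- logical(L)
    for (i in seq_len(nrow(ra))) ma[ra$start[i]:ra$end[i]] <- TRUE
    for (i in seq_len(nrow(rb))) mb[rb$start[i]:rb$end[i]] <- TRUE
    n_a <- n_a + sum(ma); n_b <- n_b + sum(mb); n_ab <- n_ab + sum(ma & mb)
  }
  un <- n_a + n_b - n_ab
  list(jaccard = if (un == 0) NA_real_ else n_ab / un,
       frac_a_in_b = if (n_a == 0) NA_real_ else n_ab / n_a,
       frac_b_in_a = if (n_b == 0) NA_real_ else n_ab / n_b)
}
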