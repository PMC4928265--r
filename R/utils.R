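# Shared low-level helpers: alphabet, smoothing, run segmentation.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes. `X` (unknown) is accepted in
#' sequences but excluded from composition-dependent computations.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

logistic <- function(x) 1 / (1 + exp(-x))

#' Centered moving average, truncated at the ends
#'
#' Smooths a numeric vector with a centered window; near the termini the
#' window is truncated to the available positions (no padding), so the output
#' has the same length as the input.
#'
#' @param x numeric vector.
#' @param window odd integer window size (>= 1).
#' @return numeric vector of `length(x)`.
#' @export
moving_average <- function(x, window) {
  stopifnot(is.numeric(x), window >= 1, window %% 2 == 1)
  n <- length(x)
  if (window == 1 || n == 0) return(x)
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Maximal runs of TRUE in a logical vector, optionally length-filtered.
# Returns a data.frame(start, end) in 1-based inclusive coordinates.
runs_from_mask <- function(mask, min_len = 1L) {
  stopifnot(is.logical(mask))
  if (length(mask) == 0 || !any(mask, na.rm = TRUE)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Validate an amino-acid sequence; returns uppercase sequence or errors with
# the first offending position. X is allowed.
check_aa_sequence <- function(sequence, id = "sequence") {
  s <- toupper(sequence)
  ch <- seq_chars(s)
  bad <- which(!ch %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0) {
    stop(sprintf("non-amino-acid character '%s' at position %d of '%s'",
                 ch[bad[1]], bad[1], id), call. = FALSE)
  }
  if (nchar(s) < 1) stop(sprintf("empty sequence for '%s'", id), call. = FALSE)
  s
}

# Derive a reproducible child seed from a base seed and a stage label.
# Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
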