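# Shared fixtures and independent brute-force oracles used across tests.
# Oracles are deliberately naive (double loops, full enumeration) and never
# call the package functions they check.

random_aa_seq <- function(n, letters = AA_ALPHABET) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Brute-force run segmentation of a threshold mask: scan left to right.
oracle_runs <- function(mask, min_len = 1) {
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) {
        out <- rbind(out, data.frame(start = as.integer(i), end = as.integer(j)))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Naive all-occurrence regex scan: test the pattern anchored at every start.
oracle_scan <- function(sequence, pattern) {
  n <- nchar(sequence)
  out <- data.frame(start = integer(0), end = integer(0))
  for (s in seq_len(n)) {
    m <- regexpr(paste0("^(?:", pattern, ")"), substring(sequence, s, n),
                 perl = TRUE)
    if (m == 1 && attr(m, "match.length") > 0) {
      out <- rbind(out, data.frame(start = s,
                                   end = s + attr(m, "match.length") - 1L))
    }
  }
  out
}

# Independent re-statement of the low-complexity trigger/extend rule:
# entropy of every window by direct counting, seeds where H <= trigger,
# flood fill across windows with H <= extend, union of window footprints,
# merge overlaps.
oracle_lcr <- function(sequence, params) {
  ch <- strsplit(sequence, "")[[1]]
  w <- params$window
  n <- length(ch)
  H <- vapply(seq_len(n - w + 1), function(i) {
    win <- ch[i:(i + w - 1)]
    win <- win[win != "X"]
    if (length(win) == 0) return(NA_real_)
    f <- table(win) / length(win)
    -sum(f * log2(f))
  }, numeric(1))
  ext <- !is.na(H) & H <= params$entropy_extend
  trig <- !is.na(H) & H <= params$entropy_trigger
  mask <- logical(n)
  for (i in seq_along(H)) {
    if (!trig[i]) next
    lo <- i; hi <- i
    while (lo > 1 && ext[lo - 1]) lo <- lo - 1
    while (hi < length(H) && ext[hi + 1]) hi <- hi + 1
    mask[lo:(hi + w - 1)] <- TRUE
  }
  oracle_runs(mask)
}

# Direct base-2 Jensen-Shannon divergence for probability vectors.
oracle_jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  kl(p, m) / 2 + kl(q, m) / 2
}

# A tiny two-protein set with hand-chosen sequences.
tiny_proteins <- function() {
  protein_set(id = c("p1", "p2"),
              sequence = c("MKKQQEDSAPK", "ACDEFGHIKLMNPQRSTVWY"),
              family = c("HKMT", "HAT"))
}

# Constant-score disorder profile for a sequence.
flat_profile <- function(pid, n, value, threshold = 0.5) {
  disorder_profile(score_track(pid, rep(value, n)), threshold = threshold)
}
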