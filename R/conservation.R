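# Alignment-column conservation (normalized Jensen-Shannon divergence,
# window 3) and constrained/flexible disorder classification.

#' Construct or read an ortholog alignment
#'
#' `ortholog_alignment()` wraps named, equal-length aligned sequences (gap
#' character `-`); `read_alignment()` reads aligned FASTA or Clustal files.
#' The reference row defaults to the first sequence.
#'
#' @param rows named character vector of aligned sequences.
#' @param reference_id id of the reference row; default the first row.
#' @return list of class `ortholog_alignment` with `rows`, `reference_id`,
#'   `n_rows`.
#' @export
ortholog_alignment <- function(rows, reference_id = NULL) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named")
  }
  if (length(unique(nchar(rows))) != 1) {
    stop("alignment rows must have equal length")
  }
  if (length(rows) < 2) stop("alignment needs >= 2 rows")
  reference_id <- reference_id %||% names(rows)[1]
  if (!reference_id %in% names(rows)) {
    stop(sprintf("reference row '%s' absent from alignment", reference_id))
  }
  structure(list(rows = toupper(rows), reference_id = reference_id,
                 n_rows = length(rows)),
            class = "ortholog_alignment")
}

#' @rdname ortholog_alignment
#' @param path aligned FASTA or Clustal file.
#' @param format `"auto"` (by extension/content), `"fasta"` or `"clustal"`.
#' @export
read_alignment <- function(path, reference_id = NULL,
                           format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^>", first)) "fasta" else "clustal"
  }
  if (format == "fasta") {
    set <- Biostrings::readAAStringSet(path)
    rows <- setNames(as.character(set),
                     vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1))
  } else {
    rows <- read_clustal_rows(path)
  }
  ortholog_alignment(rows, reference_id)
}

# Minimal Clustal block reader: skips the header, conservation and blank
# lines, concatenates per-name blocks in first-seen order. Handles the
# single-block files short alignments produce.
read_clustal_rows <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1])) {
    stop(sprintf("not a Clustal file: %s", path))
  }
  lines <- lines[-1]
  keep <- nzchar(lines) & !grepl("^\\s", lines)
  rows <- list()
  for (ln in lines[keep]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2) next
    rows[[tok[1]]] <- paste0(rows[[tok[1]]] %||% "", tok[2])
  }
  toupper(unlist(rows))
}

# Base-2 Jensen-Shannon divergence between probability vectors p and q.
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# Maximum base-2 JSD of a point-mass distribution against background q.
jsd2_pointmass_max <- function(q) {
  max(vapply(seq_along(q), function(a) {
    p <- numeric(length(q)); p[a] <- 1
    jsd2(p, q)
  }, numeric(1)))
}

#' Sequence conservation of one alignment column
#'
#' Normalized Jensen-Shannon divergence between the column's empirical
#' residue distribution and a background distribution. The raw base-2 JSD is
#' divided by the largest JSD any single-residue (fully conserved) column
#' can reach against that background, so a fully conserved column scores 1
#' against a uniform background and a column distributed like the background
#' scores 0. Columns with more than 50% gaps are uninformative and score 0.
#'
#' @param column_residues character vector of one residue per row (`-` for
#'   gaps; X ignored).
#' @param background probability vector over [AA_ALPHABET]; default uniform.
#' @return conservation score in `[0, 1]`.
#' @export
column_jsd <- function(column_residues, background = NULL) {
  ch <- toupper(column_residues)
  nongap <- ch[ch != GAP_CHAR]
  if (length(nongap) == 0) stop("all-gap column")
  if (length(nongap) / length(ch) < 0.5) return(0)
  nongap <- nongap[nongap != "X"]
  if (length(nongap) < 2) return(0)
  q <- background %||% rep(1 / 20, 20)
  stopifnot(length(q) == 20)
  cnt <- tabulate(factor(nongap, levels = AA_ALPHABET), nbins = 20)
  p <- cnt / sum(cnt)
  val <- jsd2(p, q) / jsd2_pointmass_max(q)
  min(max(val, 0), 1)
}

#' Per-reference-residue conservation track
#'
#' Computes, for every alignment column, the sequence conservation
#' ([column_jsd()]) and the disorder conservation (fraction of non-gap rows
#' whose residue at that column has disorder score at or above the
#' threshold), drops columns where the reference is gapped, projects onto
#' reference residue numbering, and smooths both signals with a centered
#' moving average of width `window` (default 3, truncated at the ends).
#'
#' @param alignment an [ortholog_alignment()].
#' @param profiles named list of [disorder_profile()], one per alignment row
#'   (on the ungapped sequences).
#' @param window smoothing window, default 3.
#' @param disorder_threshold threshold for a residue to count as disordered,
#'   default 0.5.
#' @param background background distribution passed to [column_jsd()].
#' @return data.frame of class `conservation_track` with columns `residue`
#'   (reference numbering), `column` (alignment column index), `seq_cons`,
#'   `dis_cons`; reference id and window kept as attributes.
#' @export
conservation_track <- function(alignment, profiles, window = 3,
                               disorder_threshold = 0.5, background = NULL) {
  rows <- alignment$rows
  ref_id <- alignment$reference_id
  missing_prof <- setdiff(names(rows), names(profiles))
  if (length(missing_prof) > 0) {
    stop(sprintf("no disorder profile for alignment row(s): %s",
                 paste(missing_prof, collapse = ", ")))
  }
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  n_col <- ncol(mat)
  # residue index per row per column (NA at gaps)
  res_idx <- t(apply(mat, 1, function(r) {
    ix <- cumsum(r != GAP_CHAR)
    ix[r == GAP_CHAR] <- NA
    ix
  }))
  q <- background %||% rep(1 / 20, 20)
  norm <- jsd2_pointmass_max(q)
  dis_mat <- matrix(FALSE, nrow(mat), n_col)
  for (rn in rownames(mat)) {
    v <- profiles[[rn]]$track$values
    thr <- disorder_threshold
    ix <- res_idx[rn, ]
    dis_mat[match(rn, rownames(mat)), !is.na(ix)] <- v[ix[!is.na(ix)]] >= thr
  }
  seq_cons <- numeric(n_col)
  dis_cons <- numeric(n_col)
  for (j in seq_len(n_col)) {
    col <- mat[, j]
    nongap <- col != GAP_CHAR
    if (sum(nongap) == 0) { seq_cons[j] <- 0; dis_cons[j] <- 0; next }
    dis_cons[j] <- mean(dis_mat[nongap, j])
    informative <- col[nongap & col[] != "X"]
    if (sum(nongap) / length(col) < 0.5 || length(informative) < 2) {
      seq_cons[j] <- 0
    } else {
      cnt <- tabulate(factor(informative, levels = AA_ALPHABET), nbins = 20)
      p <- cnt / sum(cnt)
      seq_cons[j] <- min(max(jsd2(p, q) / norm, 0), 1)
    }
  }
  ref_cols <- which(!is.na(res_idx[ref_id, ]))
  out <- data.frame(residue = res_idx[ref_id, ref_cols],
                    column = ref_cols,
                    seq_cons = moving_average(seq_cons[ref_cols], window),
                    dis_cons = moving_average(dis_cons[ref_cols], window))
  attr(out, "reference_id") <- ref_id
  attr(out, "window") <- window
  class(out) <- c("conservation_track", "data.frame")
  out
}

DISORDER_CONSERVATION_CLASSES <- c("CONSTRAINED_DISORDER", "FLEXIBLE_DISORDER",
                                   "NOT_CONSERVED_DISORDER", "ORDERED")

#' Classify residues as constrained or flexible disorder
#'
#' Disorder is constrained when both the disorder tendency and the sequence
#' of a region are conserved; flexible when only the disorder tendency is
#' retained. Reference-disordered residues are labelled
#' `CONSTRAINED_DISORDER` when `dis_cons >= dis_thr` and
#' `seq_cons >= seq_thr`, `FLEXIBLE_DISORDER` when only `dis_cons >=
#' dis_thr`, otherwise `NOT_CONSERVED_DISORDER`; ordered reference residues
#' are labelled `ORDERED`.
#'
#' @param track a [conservation_track()].
#' @param reference_profile the reference protein's [disorder_profile()].
#' @param dis_thr disorder-conservation threshold, default 0.75.
#' @param seq_thr sequence-conservation threshold, default 0.9.
#' @return character vector of labels, one per reference residue.
#' @export
classify_disorder_conservation <- function(track, reference_profile,
                                           dis_thr = 0.75, seq_thr = 0.9) {
  stopifnot(dis_thr >= 0, dis_thr <= 1, seq_thr >= 0, seq_thr <= 1)
  v <- reference_profile$track$values
  if (length(v) != nrow(track)) {
    stop("reference profile length does not match conservation track")
  }
  disordered <- v[track$residue] >= reference_profile$threshold
  out <- rep("NOT_CONSERVED_DISORDER", nrow(track))
  out[track$dis_cons >= dis_thr] <- "FLEXIBLE_DISORDER"
  out[track$dis_cons >= dis_thr & track$seq_cons >= seq_thr] <- "CONSTRAINED_DISORDER"
  out[!disordered] <- "ORDERED"
  out
}

#' Constrained-disorder percentage of a region
#'
#' @param classes label vector from [classify_disorder_conservation()].
#' @param region one-row region table (1-based inclusive interval).
#' @return percentage (0-100) of region residues labelled
#'   `CONSTRAINED_DISORDER`.
#' @export
constrained_percent <- function(classes, region) {
  stopifnot(nrow(region) == 1, region$end <= length(classes))
  100 * mean(classes[region$start:region$end] == "CONSTRAINED_DISORDER")
}
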