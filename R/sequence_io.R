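# Sequence, score-track, region and variant I/O. All coordinates are
# 1-based inclusive residue numbers; BED output is the only 0-based surface.

#' Construct a protein set
#'
#' A protein set is a data.frame with one row per protein: `id` (unique,
#' nonempty), `sequence` (uppercase, 20-letter alphabet plus X), and optional
#' `family` and `group` category labels.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param family,group optional category labels (recycled).
#' @return data.frame of class `protein_set`.
#' @export
protein_set <- function(id, sequence, family = NA_character_, group = NA_character_) {
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(id)) || anyNA(id)) stop("protein ids must be nonempty")
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate protein id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  sequence <- vapply(seq_along(sequence),
                     function(i) check_aa_sequence(sequence[i], id[i]),
                     character(1))
  out <- data.frame(id = id, sequence = sequence,
                    family = rep_len(as.character(family), length(id)),
                    group = rep_len(as.character(group), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

protein_lengths <- function(proteins) {
  setNames(nchar(proteins$sequence), proteins$id)
}

#' Read protein sequences from FASTA
#'
#' Description lines are parsed as `id [family=..] [group=..]`; any
#' `key=value` tokens after the id populate the corresponding columns.
#'
#' @param path path to a FASTA file.
#' @return a [protein_set()] in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  toks <- strsplit(headers, "\\s+")
  ids <- vapply(toks, `[[`, character(1), 1)
  get_kv <- function(tok, key) {
    hit <- grep(paste0("^", key, "="), tok, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
  }
  protein_set(
    id = ids,
    sequence = as.character(set),
    family = vapply(toks, get_kv, character(1), key = "family"),
    group = vapply(toks, get_kv, character(1), key = "group")
  )
}

#' Write a protein set to FASTA
#'
#' @param proteins a [protein_set()].
#' @param path output path.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- proteins$id
  fam <- ifelse(is.na(proteins$family), "", paste0(" family=", proteins$family))
  grp <- ifelse(is.na(proteins$group), "", paste0(" group=", proteins$group))
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- paste0(hdr, fam, grp)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a per-residue score track
#'
#' @param protein_id protein identifier.
#' @param values numeric vector, one finite value per residue.
#' @param source name of the predictor or generator that produced the values.
#' @return list of class `score_track` with fields `protein_id`, `values`,
#'   `source`.
#' @export
score_track <- function(protein_id, values, source = "unknown") {
  if (!all(is.finite(values))) stop("score track values must be finite")
  structure(list(protein_id = protein_id, values = as.numeric(values),
                 source = source),
            class = "score_track")
}

#' Read per-residue score tracks from TSV
#'
#' Expects columns `protein_id`, `position` (1-based) and `score`; every
#' residue of every covered protein must appear exactly once.
#'
#' @param path TSV path.
#' @param proteins the [protein_set()] the tracks belong to.
#' @param source predictor name recorded on the tracks.
#' @return named list of [score_track()], one per protein present in the file.
#' @export
read_score_tracks <- function(path, proteins, source = "external") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(tab))) {
    stop("score track file must have columns protein_id, position, score")
  }
  lens <- protein_lengths(proteins)
  unknown <- setdiff(unique(tab$protein_id), names(lens))
  if (length(unknown) > 0) {
    stop(sprintf("unknown protein id(s) in score track: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(is.finite(tab$score))) stop("non-finite score in track file")
  out <- list()
  for (pid in unique(tab$protein_id)) {
    sub <- tab[tab$protein_id == pid, ]
    L <- lens[[pid]]
    covered <- sort(sub$position)
    if (any(duplicated(covered))) {
      stop(sprintf("duplicate positions for '%s'", pid))
    }
    gaps <- setdiff(seq_len(L), covered)
    if (length(gaps) > 0) {
      stop(sprintf("missing positions for '%s': %s", pid,
                   paste(utils::head(gaps, 10), collapse = ", ")))
    }
    if (any(covered > L) || any(covered < 1)) {
      stop(sprintf("position outside 1..%d for '%s'", L, pid))
    }
    vals <- numeric(L)
    vals[sub$position] <- sub$score
    out[[pid]] <- score_track(pid, vals, source)
  }
  out
}

#' Write score tracks to TSV
#'
#' @param tracks named list of [score_track()].
#' @param path output path.
#' @export
write_score_tracks <- function(tracks, path) {
  tab <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(protein_id = tr$protein_id,
               position = seq_along(tr$values),
               score = tr$values)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

REGION_KINDS <- c("IDR", "LCR", "HOMOREPEAT", "BINDING_CANDIDATE",
                  "CONSERVED_BINDING", "CUSTOM")

#' Construct a region table
#'
#' Regions are 1-based inclusive residue intervals on a named protein with a
#' kind label and an optional score.
#'
#' @param protein_id,start,end,kind,score vectors (recycled to equal length).
#' @return data.frame with columns protein_id, start, end, kind, score.
#' @export
regions <- function(protein_id = character(0), start = integer(0),
                    end = integer(0), kind = character(0), score = NA_real_) {
  n <- max(length(start), length(end))
  if (n == 0) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(protein_id = rep_len(protein_id, n),
                    start = as.integer(rep_len(start, n)),
                    end = as.integer(rep_len(end, n)),
                    kind = rep_len(kind, n),
                    score = as.numeric(rep_len(score, n)),
                    stringsAsFactors = FALSE)
  bad <- which(out$start < 1 | out$end < out$start)
  if (length(bad) > 0) {
    stop(sprintf("invalid region interval at row %d: [%d, %d]",
                 bad[1], out$start[bad[1]], out$end[bad[1]]))
  }
  if (any(!out$kind %in% REGION_KINDS)) {
    stop(sprintf("unknown region kind; must be one of %s",
                 paste(REGION_KINDS, collapse = ", ")))
  }
  out
}

#' Validate regions against their proteins
#'
#' Checks that every region lies within `1..length(protein)`.
#'
#' @param reg region table from [regions()].
#' @param proteins a [protein_set()].
#' @return `reg`, invisibly; errors on violation.
#' @export
validate_regions <- function(reg, proteins) {
  lens <- protein_lengths(proteins)
  unknown <- setdiff(unique(reg$protein_id), names(lens))
  if (length(unknown) > 0) {
    stop(sprintf("regions reference unknown protein(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  over <- which(reg$end > lens[reg$protein_id])
  if (length(over) > 0) {
    stop(sprintf("region [%d, %d] exceeds length of '%s'",
                 reg$start[over[1]], reg$end[over[1]], reg$protein_id[over[1]]))
  }
  invisible(reg)
}

#' Convert regions to BED6
#'
#' 1-based inclusive intervals become 0-based half-open (`chromStart =
#' start - 1`, `chromEnd = end`). `name` carries the region kind; scores in
#' `[0, 1]` are scaled to the BED 0-1000 range (NA scores become 0).
#'
#' @param reg region table.
#' @return data.frame with BED6 columns.
#' @export
regions_to_bed <- function(reg) {
  sc <- reg$score
  sc[is.na(sc)] <- 0
  data.frame(chrom = reg$protein_id,
             chromStart = reg$start - 1L,
             chromEnd = reg$end,
             name = reg$kind,
             score = as.integer(round(pmin(pmax(sc, 0), 1) * 1000)),
             strand = rep(".", nrow(reg)),
             stringsAsFactors = FALSE)
}

#' @rdname regions_to_bed
#' @param bed data.frame with BED6 columns (as from [regions_to_bed()]).
#' @return for `regions_from_bed`, a region table.
#' @export
regions_from_bed <- function(bed) {
  regions(protein_id = bed$chrom, start = bed$chromStart + 1L,
          end = bed$chromEnd, kind = bed$name, score = bed$score / 1000)
}

#' Write regions as BED6
#'
#' @param reg region table.
#' @param path output path.
#' @export
write_regions_bed <- function(reg, path) {
  bed <- regions_to_bed(reg)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein variant table
#'
#' Expects TSV columns `protein_id`, `position` (1-based) and optionally
#' `annotation` (free text, e.g. the source cancer database).
#'
#' @param path TSV path.
#' @param proteins a [protein_set()] used to validate positions.
#' @return data.frame with columns protein_id, position, annotation.
#' @export
read_variants <- function(path, proteins) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "position") %in% names(tab))) {
    stop("variant file must have columns protein_id, position")
  }
  if (is.null(tab$annotation)) tab$annotation <- NA_character_
  lens <- protein_lengths(proteins)
  unknown <- setdiff(unique(tab$protein_id), names(lens))
  if (length(unknown) > 0) {
    stop(sprintf("variants reference unknown protein(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  bad <- which(tab$position < 1 | tab$position > lens[tab$protein_id])
  if (length(bad) > 0) {
    stop(sprintf("variant position %d outside '%s'",
                 tab$position[bad[1]], tab$protein_id[bad[1]]))
  }
  tab[, c("protein_id", "position", "annotation")]
}

#' Read a linear-motif class table
#'
#' Expects TSV columns `id`, `pattern` (a regular expression over the
#' amino-acid alphabet) and `tags` (comma-separated functional tags, e.g.
#' `PPI,nuclear`).
#'
#' @param path TSV path.
#' @return data.frame of class `motif_classes` with columns id, pattern, tags.
#' @export
read_motif_classes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  motif_classes(tab$id, tab$pattern, tab$tags %||% "")
}

#' @rdname read_motif_classes
#' @param id,pattern,tags vectors defining the classes directly.
#' @export
motif_classes <- function(id, pattern, tags = "") {
  if (any(duplicated(id))) stop("motif class ids must be unique")
  for (i in seq_along(pattern)) {
    ok <- tryCatch({grepl(pattern[i], "ACDEFG", perl = TRUE); TRUE},
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop(sprintf("motif pattern does not compile: %s (%s)", id[i], pattern[i]))
  }
  out <- data.frame(id = id, pattern = pattern,
                    tags = rep_len(as.character(tags), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("motif_classes", "data.frame")
  out
}
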