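# Synthetic protein families with planted ground truth: block architectures
# (ordered domains + disordered linkers), planted motifs, binding regions,
# variants, star-topology ortholog alignments and oracle score tracks.

#' Configuration for the synthetic family generator
#'
#' The defaults emulate the study system: multidomain proteins of ~900
#' residues in which long disordered linkers (here two IDR blocks of 350 and
#' 250 residues, i.e. a disorder rate close to 70%) separate ordered
#' domains; linear-motif instances and binding regions of at least 8
#' residues planted inside the linkers; clustered variants inside conserved
#' binding regions; and ortholog sets of 23 sequences (the 22-24 range
#' typical of vertebrate ortholog collections) with per-column substitution
#' classes.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   seed from it.
#' @param n_proteins number of proteins in the family, default 12.
#' @param architecture data.frame with columns `kind` (`"ordered"`/`"idr"`)
#'   and `length` giving the block layout of each protein.
#' @param length_jitter_sd relative s.d. of per-protein block-length jitter.
#' @param idr_composition,ordered_composition residue frequency vectors.
#' @param motif_plants list of plants, each a list with `id`, `pattern`,
#'   `instance` (a literal string matching the pattern), `tags`, and either
#'   `count` (instances per protein) or `density` (instances per 1000
#'   residues across the family).
#' @param binding_plants list of plants, each a list with `length` (>= 8),
#'   `conserved` (logical) and `count` (regions per protein).
#' @param n_orthologs ortholog rows per alignment (besides none — the
#'   reference is one of the rows), default 23.
#' @param sub_prob named substitution probabilities per column class
#'   (`conserved`, `ordered_bg`, `idr_bg`).
#' @param indel_prob per-column probability that an ortholog starts a short
#'   deletion (outside planted regions).
#' @param insertion_prob per-position probability of a reference-gap
#'   insertion column (outside planted regions).
#' @param variants_per_region variants planted inside each conserved binding
#'   region, default 3.
#' @param background_variants additional variants placed uniformly outside
#'   planted binding regions, per protein.
#' @param family_label family label stamped on the proteins.
#' @return list of class `family_config`.
#' @export
family_config <- function(seed = 1,
                          n_proteins = 12,
                          architecture = data.frame(
                            kind = c("ordered", "idr", "ordered", "idr"),
                            length = c(120L, 350L, 140L, 250L)),
                          length_jitter_sd = 0.08,
                          idr_composition = aa_composition_disordered,
                          ordered_composition = aa_composition_ordered,
                          motif_plants = list(
                            list(id = "LIG_SYN_A", pattern = "Q.[ED]Q",
                                 instance = "QSEQ", tags = "PPI", count = 2),
                            list(id = "MOD_SYN_B", pattern = "[ST]P.[KR]",
                                 instance = "SPAK", tags = "modification",
                                 count = 2)),
                          binding_plants = list(
                            list(length = 16L, conserved = TRUE, count = 2),
                            list(length = 10L, conserved = FALSE, count = 1)),
                          n_orthologs = 23,
                          sub_prob = c(conserved = 0, ordered_bg = 0.05,
                                       idr_bg = 0.5),
                          indel_prob = 0.01,
                          insertion_prob = 0.005,
                          variants_per_region = 3,
                          background_variants = 2,
                          family_label = "SYN") {
  stopifnot(n_proteins >= 1, n_orthologs >= 2,
            all(architecture$kind %in% c("ordered", "idr")),
            all(architecture$length >= 1),
            all(sub_prob >= 0 & sub_prob <= 1))
  for (bp in binding_plants) {
    if (bp$length < 8) stop("planted binding regions must be >= 8 residues")
  }
  structure(as.list(environment()), class = "family_config")
}

sample_comp <- function(n, comp) {
  sample(names(comp), n, replace = TRUE, prob = comp)
}

# Pick k non-overlapping spans of the given widths inside the candidate
# intervals (data.frame start/end), avoiding `taken` spans. Errors if any
# width cannot be placed.
place_spans <- function(widths, blocks, taken, what = "feature") {
  placed <- data.frame(start = integer(0), end = integer(0))
  for (w in widths) {
    ok <- FALSE
    for (try in seq_len(200)) {
      bi <- sample.int(nrow(blocks), 1)
      lo <- blocks$start[bi]; hi <- blocks$end[bi] - w + 1L
      if (hi < lo) next
      s <- sample(lo:hi, 1)
      e <- s + w - 1L
      busy <- rbind(taken, placed)
      if (nrow(busy) == 0 || all(e < busy$start | s > busy$end)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("cannot place %s of width %d inside the available blocks",
                   what, w))
    }
  }
  placed
}

#' Generate a synthetic protein family with ground truth
#'
#' Sequences are assembled block-wise (ordered blocks drawn from the
#' order-promoting composition, disordered linkers from the
#' disorder-promoting one); binding regions, motif instances and variants
#' are spliced in at recorded positions (motifs never overlap each other or
#' the binding regions, so coordinate truth stays exact). Every planted
#' motif instance is asserted to match its pattern at the recorded span.
#' Deterministic for a fixed config.
#'
#' @param config a [family_config()].
#' @return list with `proteins` (a [protein_set()]) and `truth`, a list
#'   holding `idr_regions`, `binding_regions` (with `conserved` flag),
#'   `motif_hits`, `motif_classes`, `variants`, and per-protein
#'   `column_classes` (character vector: `conserved`, `ordered_bg`,
#'   `idr_bg` per residue).
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  # feasibility: longest plant must fit the longest IDR block
  idr_blocks <- config$architecture[config$architecture$kind == "idr", ]
  if (nrow(idr_blocks) == 0) stop("architecture has no IDR block")
  max_block <- max(idr_blocks$length)
  for (mp in config$motif_plants) {
    if (nchar(mp$instance) > max_block) {
      stop(sprintf("motif instance '%s' longer than any IDR block", mp$instance))
    }
    if (!grepl(paste0("^(?:", mp$pattern, ")$"), mp$instance, perl = TRUE)) {
      stop(sprintf("instance '%s' does not match pattern '%s'",
                   mp$instance, mp$pattern))
    }
  }
  for (bp in config$binding_plants) {
    if (bp$length > max_block) stop("binding plant longer than any IDR block")
  }

  ids <- sprintf("%s%02d", tolower(config$family_label), seq_len(config$n_proteins))
  seqs <- character(config$n_proteins)
  idr_regions <- regions()
  binding_regions <- regions(); binding_conserved <- logical(0)
  motif_hits <- list()
  variants <- list()
  column_classes <- list()

  # density-mode motif plants: total instances across the family
  approx_len <- sum(config$architecture$length)
  density_counts <- lapply(config$motif_plants, function(mp) {
    if (!is.null(mp$count)) return(NULL)
    total <- config$n_proteins * approx_len
    round(mp$density * total / 1000)
  })

  for (k in seq_len(config$n_proteins)) {
    res <- withr::with_seed(derive_seed(config$seed, paste0("protein", k)), {
      arch <- config$architecture
      jitter <- pmax(0.5, 1 + rnorm(nrow(arch), 0, config$length_jitter_sd))
      lens <- as.integer(round(arch$length * jitter))
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      ch <- character(sum(lens))
      cls <- character(sum(lens))
      for (b in seq_len(nrow(arch))) {
        span <- starts[b]:ends[b]
        if (arch$kind[b] == "idr") {
          ch[span] <- sample_comp(lens[b], config$idr_composition)
          cls[span] <- "idr_bg"
        } else {
          ch[span] <- sample_comp(lens[b], config$ordered_composition)
          cls[span] <- "ordered_bg"
        }
      }
      idr_blk <- data.frame(start = starts[arch$kind == "idr"],
                            end = ends[arch$kind == "idr"])

      # binding regions first (they own their spans)
      bw <- integer(0); bcons <- logical(0)
      for (bp in config$binding_plants) {
        bw <- c(bw, rep(bp$length, bp$count))
        bcons <- c(bcons, rep(isTRUE(bp$conserved), bp$count))
      }
      bspans <- place_spans(bw, idr_blk, data.frame(start = integer(0), end = integer(0)),
                            "binding region")
      # motifs avoid binding regions and each other
      hits_k <- list()
      taken <- bspans
      for (mp in config$motif_plants) {
        cnt <- if (!is.null(mp$count)) mp$count else NA_integer_
        if (is.na(cnt)) next  # density plants handled family-wide below
        w <- nchar(mp$instance)
        sp <- place_spans(rep(w, cnt), idr_blk, taken, mp$id)
        taken <- rbind(taken, sp)
        for (r in seq_len(nrow(sp))) {
          ch[sp$start[r]:sp$end[r]] <- seq_chars(mp$instance)
          cls[sp$start[r]:sp$end[r]] <- "conserved"
          hits_k[[length(hits_k) + 1]] <- data.frame(
            motif_id = mp$id, start = sp$start[r], end = sp$end[r],
            matched = mp$instance, stringsAsFactors = FALSE)
        }
      }
      for (r in seq_len(nrow(bspans))) {
        if (bcons[r]) cls[bspans$start[r]:bspans$end[r]] <- "conserved"
      }
      # variants: clustered inside each conserved binding region + background
      vpos <- integer(0); vann <- character(0)
      for (r in which(bcons)) {
        npl <- min(config$variants_per_region,
                   bspans$end[r] - bspans$start[r] + 1L)
        pos <- sort(sample(bspans$start[r]:bspans$end[r], npl))
        vpos <- c(vpos, pos)
        vann <- c(vann, rep("planted_in_binding", npl))
      }
      if (config$background_variants > 0) {
        free <- setdiff(seq_along(ch), unlist(lapply(seq_len(nrow(bspans)),
                        function(r) bspans$start[r]:bspans$end[r])))
        pos <- sort(sample(free, config$background_variants))
        vpos <- c(vpos, pos)
        vann <- c(vann, rep("background", config$background_variants))
      }
      list(seq = paste(ch, collapse = ""), cls = cls, idr_blk = idr_blk,
           bspans = bspans, bcons = bcons,
           hits = if (length(hits_k) > 0) do.call(rbind, hits_k) else NULL,
           vpos = vpos, vann = vann)
    })
    pid <- ids[k]
    seqs[k] <- res$seq
    column_classes[[pid]] <- res$cls
    idr_regions <- rbind(idr_regions,
                         regions(pid, res$idr_blk$start, res$idr_blk$end, "IDR"))
    if (nrow(res$bspans) > 0) {
      binding_regions <- rbind(binding_regions,
                               regions(pid, res$bspans$start, res$bspans$end,
                                       "BINDING_CANDIDATE"))
      binding_conserved <- c(binding_conserved, res$bcons)
    }
    if (!is.null(res$hits)) {
      res$hits$protein_id <- pid
      motif_hits[[length(motif_hits) + 1]] <- res$hits
    }
    if (length(res$vpos) > 0) {
      variants[[length(variants) + 1]] <- data.frame(
        protein_id = pid, position = res$vpos, annotation = res$vann,
        stringsAsFactors = FALSE)
    }
  }

  # density-mode plants: spread instances across proteins round-robin
  for (mi in seq_along(config$motif_plants)) {
    mp <- config$motif_plants[[mi]]
    if (!is.null(mp$count)) next
    total <- density_counts[[mi]]
    w <- nchar(mp$instance)
    placed <- withr::with_seed(derive_seed(config$seed, paste0("density", mi)), {
      out <- list()
      for (t in seq_len(total)) {
        k <- ((t - 1) %% config$n_proteins) + 1
        pid <- ids[k]
        busy_m <- data.frame(start = integer(0), end = integer(0))
        for (h in motif_hits) {
          busy_m <- rbind(busy_m, h[h$protein_id == pid, c("start", "end")])
        }
        if (!is.null(out[[pid]])) {
          busy_m <- rbind(busy_m, out[[pid]][, c("start", "end")])
        }
        truth_b <- binding_regions[binding_regions$protein_id == pid, c("start", "end")]
        idr_blk <- idr_regions[idr_regions$protein_id == pid, c("start", "end")]
        sp <- place_spans(w, idr_blk, rbind(busy_m, truth_b), mp$id)
        rec <- data.frame(motif_id = mp$id, start = sp$start, end = sp$end,
                          matched = mp$instance, protein_id = pid,
                          stringsAsFactors = FALSE)
        out[[pid]] <- rbind(out[[pid]], rec)
      }
      out
    })
    for (pid in names(placed)) {
      for (r in seq_len(nrow(placed[[pid]]))) {
        s <- placed[[pid]]$start[r]; e <- placed[[pid]]$end[r]
        k <- match(pid, ids)
        ch <- seq_chars(seqs[k])
        ch[s:e] <- seq_chars(mp$instance)
        seqs[k] <- paste(ch, collapse = "")
        column_classes[[pid]][s:e] <- "conserved"
      }
      motif_hits[[length(motif_hits) + 1]] <- placed[[pid]]
    }
  }

  proteins <- protein_set(ids, seqs, family = config$family_label)
  hits <- if (length(motif_hits) > 0) {
    h <- do.call(rbind, motif_hits)
    h <- h[order(match(h$protein_id, ids), h$start, h$motif_id),
           c("motif_id", "protein_id", "start", "end", "matched")]
    rownames(h) <- NULL
    h
  } else {
    data.frame(motif_id = character(0), protein_id = character(0),
               start = integer(0), end = integer(0), matched = character(0))
  }
  # consistency assertion: every planted instance matches in place
  for (r in seq_len(nrow(hits))) {
    sub <- substring(proteins$sequence[match(hits$protein_id[r], ids)],
                     hits$start[r], hits$end[r])
    pat <- config$motif_plants[[which(vapply(config$motif_plants, `[[`,
                                             character(1), "id") == hits$motif_id[r])]]$pattern
    stopifnot(identical(sub, hits$matched[r]),
              grepl(paste0("^(?:", pat, ")$"), sub, perl = TRUE))
  }
  binding_regions$conserved <- binding_conserved
  classes <- motif_classes(
    id = vapply(config$motif_plants, `[[`, character(1), "id"),
    pattern = vapply(config$motif_plants, `[[`, character(1), "pattern"),
    tags = vapply(config$motif_plants, function(mp) mp$tags %||% "", character(1)))
  list(proteins = proteins,
       truth = list(idr_regions = idr_regions,
                    binding_regions = binding_regions,
                    motif_hits = hits,
                    motif_classes = classes,
                    variants = if (length(variants) > 0) do.call(rbind, variants)
                               else data.frame(protein_id = character(0),
                                               position = integer(0),
                                               annotation = character(0)),
                    column_classes = column_classes,
                    config = config))
}

#' Generate a star-topology ortholog alignment for one protein
#'
#' Orthologs are derived from the reference by independent per-column
#' substitution with a class-specific probability (0 for `conserved`
#' columns), with replacement residues drawn from the block-appropriate
#' composition so that disordered columns stay compositionally disordered.
#' Short deletions (orthologs gapped) and insertion columns (reference
#' gapped) are introduced only outside planted regions, so planted
#' coordinate truth stays exact.
#'
#' @param family result of [generate_family()].
#' @param protein_id which protein to build the alignment for.
#' @param n_orthologs,sub_prob,indel_prob,insertion_prob override the
#'   config values.
#' @param scramble_idr if TRUE, disordered background columns are
#'   substituted with probability 1 (composition-preserving scrambling:
#'   disorder tendency retained, sequence not).
#' @return an [ortholog_alignment()] whose reference row is the input
#'   protein.
#' @export
generate_ortholog_alignment <- function(family, protein_id,
                                        n_orthologs = NULL, sub_prob = NULL,
                                        indel_prob = NULL, insertion_prob = NULL,
                                        scramble_idr = FALSE) {
  config <- family$truth$config
  n_orthologs <- n_orthologs %||% config$n_orthologs
  sub_prob <- sub_prob %||% config$sub_prob
  indel_prob <- indel_prob %||% config$indel_prob
  insertion_prob <- insertion_prob %||% config$insertion_prob
  k <- match(protein_id, family$proteins$id)
  if (is.na(k)) stop(sprintf("unknown protein '%s'", protein_id))
  ref <- seq_chars(family$proteins$sequence[k])
  cls <- family$truth$column_classes[[protein_id]]
  L <- length(ref)
  withr::with_seed(derive_seed(config$seed, paste0("aln", protein_id)), {
    p_sub <- unname(sub_prob[cls])
    if (scramble_idr) p_sub[cls == "idr_bg"] <- 1
    rows <- matrix(GAP_CHAR, n_orthologs + 1, L)
    rows[1, ] <- ref
    for (o in seq_len(n_orthologs)) {
      orth <- ref
      do_sub <- runif(L) < p_sub
      if (any(do_sub)) {
        idr_sub <- do_sub & cls == "idr_bg"
        ord_sub <- do_sub & cls != "idr_bg"
        if (any(idr_sub)) orth[idr_sub] <- sample_comp(sum(idr_sub),
                                                       config$idr_composition)
        if (any(ord_sub)) orth[ord_sub] <- sample_comp(sum(ord_sub),
                                                       config$ordered_composition)
      }
      # short deletions outside planted (conserved) columns
      del_start <- which(runif(L) < indel_prob & cls != "conserved")
      for (s in del_start) {
        dlen <- sample(1:3, 1)
        span <- s:min(L, s + dlen - 1L)
        span <- span[cls[span] != "conserved"]
        orth[span] <- GAP_CHAR
      }
      rows[o + 1, ] <- orth
    }
    # insertion columns (reference gapped) after eligible positions
    ins_after <- which(runif(L) < insertion_prob & cls == "idr_bg")
    if (length(ins_after) > 0) {
      pieces <- list()
      prev <- 0L
      for (s in sort(ins_after)) {
        pieces[[length(pieces) + 1]] <- rows[, (prev + 1L):s, drop = FALSE]
        ins_col <- matrix(GAP_CHAR, n_orthologs + 1, 1)
        has_res <- runif(n_orthologs) < 0.5
        ins_col[which(has_res) + 1, 1] <- sample_comp(sum(has_res),
                                                      config$idr_composition)
        pieces[[length(pieces) + 1]] <- ins_col
        prev <- s
      }
      if (prev < L) pieces[[length(pieces) + 1]] <- rows[, (prev + 1L):L, drop = FALSE]
      rows <- do.call(cbind, pieces)
    }
    aligned <- apply(rows, 1, paste, collapse = "")
    names(aligned) <- c(protein_id, sprintf("ortho%02d", seq_len(n_orthologs)))
    ortholog_alignment(aligned, reference_id = protein_id)
  })
}

#' Oracle score tracks from planted truth
#'
#' Per-residue tracks set to `inside` (default 0.9) within planted regions
#' and `outside` (default 0.1) elsewhere, with optional Gaussian jitter
#' clipped to `[0, 1]`. These oracle tracks let every downstream stage be
#' tested independently of the built-in stand-in predictors.
#'
#' @param family result of [generate_family()].
#' @param what `"disorder"` (planted IDRs) or `"binding"` (planted binding
#'   regions).
#' @param inside,outside track values inside/outside planted regions.
#' @param jitter_sd Gaussian jitter s.d. (<= 0.05 recommended), default 0.
#' @param seed seed for the jitter; defaults to the family seed.
#' @return named list of [score_track()], one per protein.
#' @export
generate_truth_tracks <- function(family, what = c("disorder", "binding"),
                                  inside = 0.9, outside = 0.1,
                                  jitter_sd = 0, seed = NULL) {
  what <- match.arg(what)
  reg <- if (what == "disorder") family$truth$idr_regions
         else family$truth$binding_regions
  seed <- seed %||% derive_seed(family$truth$config$seed, paste0("track", what))
  withr::with_seed(seed, {
    out <- list()
    for (k in seq_len(nrow(family$proteins))) {
      pid <- family$proteins$id[k]
      L <- nchar(family$proteins$sequence[k])
      v <- rep(outside, L)
      sub <- reg[reg$protein_id == pid, ]
      for (i in seq_len(nrow(sub))) v[sub$start[i]:sub$end[i]] <- inside
      if (jitter_sd > 0) v <- pmin(pmax(v + rnorm(L, 0, jitter_sd), 0), 1)
      out[[pid]] <- score_track(pid, v, source = paste0("truth_", what))
    }
    out
  })
}

#' Generate a synthetic torsion ensemble
#'
#' Builds `n_frames` backbone conformations of `n_res` residues: the first
#' `round(helix_fraction * n_frames)` frames are ideal alpha helices
#' (phi -57, psi -47), the rest extended chains (phi -120, psi 120).
#' Optional Gaussian torsion noise.
#'
#' @param n_res residues per chain.
#' @param n_frames number of frames.
#' @param helix_fraction fraction of helical frames.
#' @param noise_sd torsion noise s.d. in degrees, default 0.
#' @param seed seed for the noise.
#' @return list with `frames` (list of `torsion_frame`) and `models`
#'   (coordinate matrices, writable via [write_multimodel_pdb()]).
#' @export
generate_structure_ensemble <- function(n_res = 30, n_frames = 20,
                                        helix_fraction = 1, noise_sd = 0,
                                        seed = 1) {
  n_helix <- round(helix_fraction * n_frames)
  withr::with_seed(seed, {
    models <- lapply(seq_len(n_frames), function(m) {
      if (m <= n_helix) {
        phi <- rep(-57, n_res); psi <- rep(-47, n_res)
      } else {
        phi <- rep(-120, n_res); psi <- rep(120, n_res)
      }
      if (noise_sd > 0) {
        phi <- phi + rnorm(n_res, 0, noise_sd)
        psi <- psi + rnorm(n_res, 0, noise_sd)
      }
      build_backbone(phi, psi)
    })
    frames <- lapply(seq_along(models),
                     function(m) backbone_torsions(models[[m]], frame_index = m))
    list(frames = frames, models = models)
  })
}
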