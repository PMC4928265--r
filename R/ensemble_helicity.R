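# Backbone torsions from multi-model structures and per-residue
# alpha-helix occupancy across a conformational ensemble.

# Signed dihedral angle (degrees, in (-180, 180]) defined by points
# p1-p2-p3-p4, using the atan2 formulation.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi torsions from backbone coordinates
#'
#' `coords` holds the N, CA, C atoms of consecutive residues as a
#' `(3 * n_res) x 3` matrix (rows in N, CA, C order). Rows with any NA
#' coordinate flag the atom as missing; torsions involving a missing atom
#' are NA. The first residue's phi and the last residue's psi are undefined
#' (NA).
#'
#' @param coords numeric matrix of backbone coordinates.
#' @param frame_index frame label stored on the result.
#' @return list of class `torsion_frame` with `frame_index` and numeric
#'   vectors `phi`, `psi` (degrees, one per residue).
#' @export
backbone_torsions <- function(coords, frame_index = 1L) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) %% 3 == 0)
  n_res <- nrow(coords) %/% 3
  at <- function(i, name) {
    row <- (i - 1) * 3 + match(name, c("N", "CA", "C"))
    coords[row, ]
  }
  phi <- rep(NA_real_, n_res)
  psi <- rep(NA_real_, n_res)
  ok <- function(...) !anyNA(c(...))
  for (i in seq_len(n_res)) {
    if (i > 1) {
      pts <- list(at(i - 1, "C"), at(i, "N"), at(i, "CA"), at(i, "C"))
      if (ok(unlist(pts))) phi[i] <- dihedral4(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
    if (i < n_res) {
      pts <- list(at(i, "N"), at(i, "CA"), at(i, "C"), at(i + 1, "N"))
      if (ok(unlist(pts))) psi[i] <- dihedral4(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
  }
  structure(list(frame_index = frame_index, phi = phi, psi = psi),
            class = "torsion_frame")
}

#' Torsion frames from a multi-model PDB file
#'
#' Reads a multi-model structure (e.g. a conformational ensemble) and
#' computes phi/psi per residue for every model from the N, CA, C backbone
#' atoms. Residues with missing backbone atoms are flagged (NA torsions),
#' not fatal.
#'
#' @param path PDB file path.
#' @return list of `torsion_frame`, one per model.
#' @export
torsions_from_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, elety = c("N", "CA", "C"), verbose = FALSE)
  atoms <- pdb$atom[sel$atom, ]
  resnos <- sort(unique(atoms$resno))
  n_res <- length(resnos)
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(m) {
    coords <- matrix(NA_real_, n_res * 3, 3)
    for (k in seq_len(nrow(atoms))) {
      i <- match(atoms$resno[k], resnos)
      j <- match(atoms$elety[k], c("N", "CA", "C"))
      xyz_idx <- (sel$atom[k] - 1) * 3 + 1:3
      coords[(i - 1) * 3 + j, ] <- pdb$xyz[m, xyz_idx]
    }
    backbone_torsions(coords, frame_index = m)
  })
}

#' Alpha-helical torsion basin
#'
#' Torsion-angle box counted as helical. The default is a generous basin
#' around the canonical alpha-helix torsions (phi -57, psi -47).
#'
#' @param phi_min,phi_max,psi_min,psi_max basin bounds in degrees.
#' @return list of class `alpha_basin`.
#' @export
alpha_basin <- function(phi_min = -90, phi_max = -30,
                        psi_min = -77, psi_max = -17) {
  stopifnot(phi_min < phi_max, psi_min < psi_max)
  structure(list(phi_min = phi_min, phi_max = phi_max,
                 psi_min = psi_min, psi_max = psi_max),
            class = "alpha_basin")
}

in_basin <- function(frame, basin) {
  frame$phi >= basin$phi_min & frame$phi <= basin$phi_max &
    frame$psi >= basin$psi_min & frame$psi <= basin$psi_max
}

#' Per-residue helix occupancy across an ensemble
#'
#' For every residue, the fraction of frames whose (phi, psi) fall inside
#' the alpha basin. Frames where a residue's torsions are undefined are
#' excluded from both numerator and denominator for that residue; residues
#' with no usable frame get NA occupancy.
#'
#' @param frames list of `torsion_frame` (see [torsions_from_models()]).
#' @param basin an [alpha_basin()].
#' @return list of class `helicity_profile` with `occupancy` (per residue),
#'   `n_frames`, `n_usable` (per residue) and `alpha_basin`.
#' @export
helicity_profile <- function(frames, basin = alpha_basin()) {
  stopifnot(length(frames) >= 1)
  n_res <- length(frames[[1]]$phi)
  helix_count <- integer(n_res)
  usable <- integer(n_res)
  for (fr in frames) {
    stopifnot(length(fr$phi) == n_res)
    defined <- !is.na(fr$phi) & !is.na(fr$psi)
    hit <- defined & in_basin(fr, basin)
    usable <- usable + defined
    helix_count <- helix_count + hit
  }
  occ <- ifelse(usable > 0, helix_count / usable, NA_real_)
  structure(list(occupancy = occ, n_frames = length(frames),
                 n_usable = usable, alpha_basin = basin),
            class = "helicity_profile")
}

#' Contiguous helical runs within one frame
#'
#' Maximal runs of residues whose torsions fall in the alpha basin, kept at
#' length `min_run` or more — distinguishes continuous helices from
#' isolated helical residues.
#'
#' @param frame a `torsion_frame`.
#' @param basin an [alpha_basin()].
#' @param min_run minimum run length, default 4.
#' @param protein_id label for the output regions.
#' @return region table of kind `CUSTOM`; `score` is the run length.
#' @export
contiguous_helix_runs <- function(frame, basin = alpha_basin(), min_run = 4,
                                  protein_id = "model") {
  stopifnot(min_run >= 1)
  mask <- in_basin(frame, basin)
  mask[is.na(mask)] <- FALSE
  r <- runs_from_mask(mask, min_len = min_run)
  if (nrow(r) == 0) return(regions())
  regions(protein_id, r$start, r$end, "CUSTOM", as.numeric(r$end - r$start + 1L))
}

# --- backbone construction (used to build synthetic ensembles) -----------

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D bond
# angle (degrees) and the A-B-C-D torsion (degrees); standard NeRF.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  nxbc <- c(n[2] * bc[3] - n[3] * bc[2],
            n[3] * bc[1] - n[1] * bc[3],
            n[1] * bc[2] - n[2] * bc[1])
  M <- cbind(bc, nxbc, n)
  as.numeric(M %*% d2 + c)
}

#' Build backbone coordinates from phi/psi torsions
#'
#' Constructs N, CA, C coordinates for a chain with the given backbone
#' torsions (ideal bond lengths/angles, omega fixed at 180). `phi[1]` and
#' `psi[n]` are undefined and ignored. The inverse of
#' [backbone_torsions()]: recomputing torsions from the built chain returns
#' the inputs.
#'
#' @param phi,psi numeric vectors of equal length (degrees).
#' @return `(3 * n_res) x 3` coordinate matrix (rows N, CA, C per residue).
#' @export
build_backbone <- function(phi, psi) {
  stopifnot(length(phi) == length(psi), length(phi) >= 2)
  n_res <- length(phi)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- matrix(NA_real_, n_res * 3, 3)
  # first residue: N at origin, CA on x axis, C in the xy plane
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(b_nca, 0, 0)
  ang <- a_ncac * pi / 180
  coords[3, ] <- coords[2, ] + b_cac * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n_res - 1)) {
    nN <- coords[(i - 1) * 3 + 1, ]; nCA <- coords[(i - 1) * 3 + 2, ]
    nC <- coords[(i - 1) * 3 + 3, ]
    N2 <- nerf_place(nN, nCA, nC, b_cn, a_cacn, psi[i])
    CA2 <- nerf_place(nCA, nC, N2, b_nca, a_cnca, 180)
    C2 <- nerf_place(nC, N2, CA2, b_cac, a_ncac, phi[i + 1])
    coords[i * 3 + 1, ] <- N2
    coords[i * 3 + 2, ] <- CA2
    coords[i * 3 + 3, ] <- C2
  }
  coords
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' @param models list of backbone coordinate matrices (as from
#'   [build_backbone()]).
#' @param path output path.
#' @param chain chain identifier.
#' @export
write_multimodel_pdb <- function(models, path, chain = "A") {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    coords <- models[[m]]
    n_res <- nrow(coords) %/% 3
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_len(n_res)) {
      for (j in 1:3) {
        serial <- serial + 1L
        xyz <- coords[(i - 1) * 3 + j, ]
        if (anyNA(xyz)) next
        name <- c(" N  ", " CA ", " C  ")[j]
        writeLines(sprintf(
          "ATOM  %5d %s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, name, chain, i, xyz[1], xyz[2], xyz[3],
          c("N", "C", "C")[j]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
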