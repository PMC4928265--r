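# Residue-level propensity scales and background compositions used by the
# stand-in predictors and the synthetic-family generator.

#' Disorder propensity scale (TOP-IDP)
#'
#' Per-residue disorder propensities from the TOP-IDP scale (Campen et al.,
#' 2008), ordered from the most order-promoting (W) to the most
#' disorder-promoting (P). Used as the default composition scale of
#' [predict_disorder_standin()].
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
disorder_propensity <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
  L = -0.326, V = -0.121, N =  0.007, C =  0.020, T =  0.059,
  A =  0.060, G =  0.166, R =  0.180, D =  0.192, H =  0.303,
  Q =  0.318, S =  0.341, K =  0.586, E =  0.736, P =  0.987
)

#' Interface propensity scale
#'
#' A heuristic per-residue interface-formation propensity: aromatic and
#' aliphatic residues that commonly anchor binding interfaces score high,
#' structure-breaking and highly polar residues score low. Used by the
#' built-in binding-propensity predictor ([predict_binding_standin()]) to
#' pick out disordered segments enriched in interaction-prone residues.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
interface_propensity <- c(
  W =  1.00, F =  0.90, Y =  0.85, L =  0.70, I =  0.65,
  M =  0.60, V =  0.50, R =  0.45, C =  0.40, H =  0.35,
  K =  0.20, T =  0.10, A =  0.10, N =  0.05, Q =  0.05,
  S =  0.00, D =  0.00, E = -0.05, G = -0.10, P = -0.20
)

#' Background residue compositions for disordered and ordered segments
#'
#' Residue frequency vectors used by the synthetic-family generator:
#' `aa_composition_disordered` is enriched in disorder-promoting residues
#' (P, E, S, Q, K) and depleted in order-promoting ones (W, C, F, I, Y, V);
#' `aa_composition_ordered` is the converse. The frequencies follow the
#' qualitative composition bias reported for disordered regions; they are
#' configuration data, not fitted constants.
#'
#' @format Named numeric probability vector over the 20 standard residues.
#' @export
aa_composition_disordered <- c(
  P = 0.100, E = 0.120, S = 0.120, Q = 0.100, K = 0.100,
  G = 0.080, A = 0.060, D = 0.050, T = 0.050, R = 0.050,
  N = 0.040, H = 0.020, L = 0.030, M = 0.015, V = 0.020,
  I = 0.015, F = 0.010, Y = 0.010, C = 0.005, W = 0.005
)

#' @rdname aa_composition_disordered
#' @export
aa_composition_ordered <- c(
  L = 0.110, V = 0.100, I = 0.090, F = 0.070, Y = 0.050,
  W = 0.040, C = 0.030, M = 0.040, A = 0.080, G = 0.050,
  T = 0.060, S = 0.040, N = 0.040, D = 0.040, E = 0.030,
  Q = 0.020, K = 0.030, R = 0.040, H = 0.030, P = 0.010
)
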