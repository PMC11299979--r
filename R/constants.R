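#' Physical constants used throughout the package
#'
#' @description
#' `GAS_CONSTANT_KCAL` is the molar gas constant in kcal/(mol K) used for
#' all free-energy conversions (two-state unfolding, proteolysis
#' energetics, Boltzmann inversion of trajectory histograms).
#'
#' @format A numeric scalar, 1.987e-3 kcal/(mol K).
#' @export
GAS_CONSTANT_KCAL <- 1.987e-3

#' Spin constants for backbone amide 15N relaxation
#'
#' Standard values for the 1H-15N spin pair: gyromagnetic ratios
#' (rad s-1 T-1), the reduced Planck constant (J s), mu0/4pi (T m A-1),
#' the N-H bond length (m) and the 15N chemical shift anisotropy
#' (dimensionless). Isotropic overall tumbling is assumed everywhere.
#'
#' @format Named list.
#' @export
NMR_CONSTANTS <- list(
  gamma_h = 2.6752218744e8,
  gamma_n = -2.7126e7,
  hbar    = 1.054571817e-34,
  mu0_4pi = 1e-7,
  r_nh    = 1.02e-10,
  csa     = -160e-6
)

#' Canonical beta-grasp segment map (ubiquitin numbering)
#'
#' Default secondary-structure segments for segment-averaged comparisons
#' of temperature coefficients and conformational entropy between
#' beta-grasp (ubiquitin-like) proteins. Boundaries follow the canonical
#' ubiquitin topology; override with your own map for other constructs.
#'
#' @return Named list mapping segment name to an integer vector of
#'   residue numbers.
#' @examples
#' ubiquitin_segments()$beta1
#' @export
ubiquitin_segments <- function() {
  list(
    beta1       = 2:7,
    beta2       = 11:17,
    alpha1      = 23:34,
    beta3       = 40:45,
    beta4       = 48:50,
    alpha2_loop = 51:63,
    beta5       = 66:71
  )
}

# internal: consistent spec validation error
spec_error <- function(msg) stop("invalid spec: ", msg, call. = FALSE)
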