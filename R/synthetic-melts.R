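#' Specification of a synthetic equilibrium-unfolding melt
#'
#' Ground-truth parameters for a two-state denaturation curve. In
#' chemical mode the unfolding free energy follows the linear
#' extrapolation model dG([D]) = dG0 - m [D] at the stated temperature;
#' in thermal mode the signal is a normalized sigmoid with midpoint `tm`
#' and width `slope_t`.
#'
#' @param dG0 unfolding free energy at zero denaturant (kcal/mol), > 0.
#' @param m_value denaturant dependence of dG (kcal/mol/M), > 0.
#' @param axis strictly increasing denaturant concentrations (M) or
#'   temperatures (degrees C). Defaults: 0-6 M GdnCl in 0.2 M steps
#'   (chemical), 20-95 C in 1 C steps (thermal).
#' @param tm thermal midpoint (degrees C); thermal mode only.
#' @param slope_t thermal transition width (degrees C).
#' @param noise_sd Gaussian noise sd on the normalized signal.
#' @param baselines list with `folded = c(intercept, slope)` and
#'   `unfolded = c(intercept, slope)` linear baselines applied to the
#'   fraction-unfolded signal. Defaults to flat 0/1 baselines, i.e. a
#'   normalized curve.
#' @param temperature_k temperature of the chemical melt (K).
#' @param seed RNG seed; generation is bit-reproducible under it.
#' @return An object of class `melt_spec`.
#' @export
melt_spec <- function(dG0 = NULL, m_value = NULL, axis = NULL,
                      tm = NULL, slope_t = 3, noise_sd = 0,
                      baselines = list(folded = c(0, 0), unfolded = c(1, 0)),
                      temperature_k = 298, seed = 1L) {
  if (!is.null(dG0) && dG0 <= 0) spec_error("dG0 must be > 0")
  if (!is.null(m_value) && m_value <= 0) spec_error("m_value must be > 0")
  if (noise_sd < 0) spec_error("noise_sd must be >= 0")
  if (!is.null(axis) && any(diff(axis) <= 0))
    spec_error("axis must be strictly increasing")
  structure(list(dG0 = dG0, m_value = m_value, axis = axis, tm = tm,
                 slope_t = slope_t, noise_sd = noise_sd,
                 baselines = baselines, temperature_k = temperature_k,
                 seed = as.integer(seed)),
            class = "melt_spec")
}

new_denaturation_curve <- function(axis, signal, mode, normalized,
                                   truth = NULL) {
  structure(list(axis = axis, signal = signal, mode = mode,
                 normalized = normalized, truth = truth),
            class = "denaturation_curve")
}

#' @export
print.denaturation_curve <- function(x, ...) {
  cat(sprintf("<denaturation_curve> mode=%s, %d points, axis [%g, %g]%s\n",
              x$mode, length(x$axis), min(x$axis), max(x$axis),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Simulate a chemical (denaturant) equilibrium-unfolding curve
#'
#' Forward model of a two-state melt under the linear extrapolation
#' model: dG([D]) = dG0 - m [D], fraction unfolded
#' f_u = 1 / (1 + exp(dG/RT)), mixed with the folded/unfolded baselines
#' and perturbed by additive Gaussian noise. The ground-truth spec is
#' retained in the returned object so fitters can be scored by
#' parameter recovery.
#'
#' @param spec a [melt_spec()] with `dG0` and `m_value` set.
#' @return A `denaturation_curve` (mode `"chemical"`) with fields
#'   `axis` (M), `signal`, `normalized` and `truth`.
#' @examples
#' sp <- melt_spec(dG0 = 5, m_value = 2, noise_sd = 0)
#' cv <- gen_chemical_melt(sp)
#' # midpoint Cm = dG0/m = 2.5 M, where the signal crosses 0.5
#' @export
gen_chemical_melt <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  if (is.null(spec$dG0) || is.null(spec$m_value))
    spec_error("chemical melt needs dG0 and m_value")
  axis <- if (is.null(spec$axis)) seq(0, 6, by = 0.2) else spec$axis
  rt <- GAS_CONSTANT_KCAL * spec$temperature_k
  dg <- spec$dG0 - spec$m_value * axis
  fu <- 1 / (1 + exp(dg / rt))
  bf <- spec$baselines$folded
  bu <- spec$baselines$unfolded
  sig <- (bf[1] + bf[2] * axis) * (1 - fu) + (bu[1] + bu[2] * axis) * fu
  normalized <- identical(unname(bf), c(0, 0)) && identical(unname(bu), c(1, 0))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    sig <- sig + rnorm(length(axis), 0, spec$noise_sd)
  }
  new_denaturation_curve(axis, sig, "chemical", normalized, truth = spec)
}

#' Simulate a thermal equilibrium-unfolding curve
#'
#' Normalized sigmoidal melt f_u(T) = 1 / (1 + exp((tm - T)/slope_t))
#' on a 20-95 C grid at 1 C steps by default, plus Gaussian noise.
#'
#' @param spec a [melt_spec()] with `tm` set; `slope_t` is the
#'   transition width (degrees C; the limit `slope_t -> 0` is a step).
#' @return A `denaturation_curve` (mode `"thermal"`).
#' @export
gen_thermal_melt <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  if (is.null(spec$tm)) spec_error("thermal melt needs tm")
  axis <- if (is.null(spec$axis)) seq(20, 95, by = 1) else spec$axis
  if (spec$tm < min(axis) || spec$tm > max(axis))
    spec_error("tm outside the temperature axis")
  fu <- if (spec$slope_t <= 0) as.numeric(axis >= spec$tm)
        else 1 / (1 + exp((spec$tm - axis) / spec$slope_t))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    fu <- fu + rnorm(length(axis), 0, spec$noise_sd)
  }
  new_denaturation_curve(axis, fu, "thermal", TRUE, truth = spec)
}
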