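#' Two-state equilibrium unfolding fits
#'
#' @description
#' Chemical denaturation curves are analysed with the linear
#' extrapolation model: the unfolding free energy at denaturant
#' concentration \[D\] is dG(\[D\]) = dG0 - m \[D\], and the apparent
#' fraction unfolded is f_u = 1 / (1 + exp(dG/RT)). Fitting a melt
#' therefore returns the zero-denaturant free energy dG0 (kcal/mol),
#' the m-value (kcal/mol/M) and the midpoint Cm = dG0/m (M). Thermal
#' melts are fitted with an empirical four-parameter logistic to yield
#' the melting temperature Tm.
#'
#' @name unfolding
NULL

rt_kcal <- function(temperature_k) GAS_CONSTANT_KCAL * temperature_k

two_state_fraction <- function(d, dG0, m, rt) 1 / (1 + exp((dG0 - m * d) / rt))

# baseline-mixed observable for un-normalized melts
two_state_signal <- function(d, dG0, m, bf0, bf1, bu0, bu1, rt) {
  fu <- two_state_fraction(d, dG0, m, rt)
  (bf0 + bf1 * d) * (1 - fu) + (bu0 + bu1 * d) * fu
}

new_two_state_fit <- function(dG0, m_value, baselines, se, rss,
                              temperature_k, flags = character()) {
  structure(list(dG0 = dG0, m_value = m_value, cm = dG0 / m_value,
                 baselines = baselines, se = se, rss = rss,
                 temperature_k = temperature_k, flags = flags),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<two_state_fit> dG0 = %.3f +/- %.3f kcal/mol, m = %.3f kcal/mol/M, Cm = %.3f M\n",
    x$dG0, x$se[["dG0"]], x$m_value, x$cm))
  invisible(x)
}

# endpoint-derived starting values for (dG0, m): Cm from the 0.5
# crossing of the normalized signal, m from the slope there
# (df_u/dD at Cm equals m / 4RT)
melt_start_values <- function(axis, frac, rt) {
  ord <- order(axis)
  axis <- axis[ord]; frac <- frac[ord]
  cross <- which(diff(sign(frac - 0.5)) != 0)
  cm <- if (length(cross) > 0) {
    i <- cross[1]
    axis[i] + (0.5 - frac[i]) * (axis[i + 1] - axis[i]) /
      (frac[i + 1] - frac[i])
  } else axis[which.min(abs(frac - 0.5))]
  span <- max(axis) - min(axis)
  slope <- (frac[min(length(frac), which.min(abs(axis - cm)) + 1)] -
            frac[max(1, which.min(abs(axis - cm)) - 1)]) /
           (2 * span / (length(axis) - 1))
  m0 <- max(4 * rt * abs(slope), 0.2)
  list(cm = cm, m0 = m0)
}

#' Fit a chemical denaturation curve to the two-state model
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of
#' f_u(\[D\]) = 1 / (1 + exp((dG0 - m \[D\]) / RT)). Curves flagged as
#' normalized are fitted with the pure two-parameter model; raw curves
#' co-fit linear folded/unfolded baselines. Multi-start initial guesses
#' are derived from the midpoint crossing and endpoint slopes.
#'
#' @param curve a `denaturation_curve` in chemical mode.
#' @param temperature_k temperature (K) used in the Boltzmann factor;
#'   default 298 K.
#' @return A `two_state_fit` with `dG0`, `m_value`, `cm` (= dG0/m,
#'   exact identity), `baselines`, standard errors `se`, `rss` and any
#'   warning `flags` (e.g. transition close to the edge of the sampled
#'   range).
#' @examples
#' cv <- gen_chemical_melt(melt_spec(dG0 = 5, m_value = 2))
#' fit <- fit_chemical_two_state(cv)
#' c(fit$dG0, fit$m_value, fit$cm)
#' @export
fit_chemical_two_state <- function(curve, temperature_k = 298) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (curve$mode != "chemical") stop("curve is not in chemical mode")
  if (length(curve$axis) < 8) stop("need >= 8 points spanning the transition")
  rt <- rt_kcal(temperature_k)
  d <- curve$axis; y <- curve$signal
  st <- melt_start_values(d, if (isTRUE(curve$normalized)) y else
                               (y - min(y)) / (max(y) - min(y)), rt)
  starts <- expand.grid(cm = unique(c(st$cm, mean(range(d)))),
                        m0 = unique(c(st$m0, 1, 2)))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- if (isTRUE(curve$normalized)) {
      list(dG0 = starts$m0[i] * starts$cm[i], m = starts$m0[i])
    } else {
      list(dG0 = starts$m0[i] * starts$cm[i], m = starts$m0[i],
           bf0 = y[1], bf1 = 0, bu0 = y[length(y)], bu1 = 0)
    }
    fml <- if (isTRUE(curve$normalized)) {
      y ~ two_state_fraction(d, dG0, m, rt)
    } else {
      y ~ two_state_signal(d, dG0, m, bf0, bf1, bu0, bu1, rt)
    }
    cand <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(d = d, y = y),
                        start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || deviance(cand) < deviance(fit))) fit <- cand
  }
  if (is.null(fit))
    stop("two-state fit failed to converge (no viable start; ",
         "check that the curve shows a transition)")
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  if (cf[["dG0"]] <= 0 || cf[["m"]] <= 0)
    stop("two-state fit converged to non-physical parameters ",
         sprintf("(dG0 = %.3g, m = %.3g)", cf[["dG0"]], cf[["m"]]))
  cm <- cf[["dG0"]] / cf[["m"]]
  flags <- character()
  if (cm < min(d) || cm > max(d))
    flags <- c(flags, "transition midpoint outside sampled range")
  baselines <- if (isTRUE(curve$normalized)) {
    list(folded = c(0, 0), unfolded = c(1, 0))
  } else {
    list(folded = c(cf[["bf0"]], cf[["bf1"]]),
         unfolded = c(cf[["bu0"]], cf[["bu1"]]))
  }
  if (length(flags)) warning(paste(flags, collapse = "; "), call. = FALSE)
  new_two_state_fit(cf[["dG0"]], cf[["m"]], baselines,
                    c(dG0 = unname(se["dG0"]), m_value = unname(se["m"])),
                    deviance(fit), temperature_k, flags)
}

#' Map a raw melt to apparent fraction unfolded
#'
#' Removes folded/unfolded baselines so the signal lies in \[0, 1\].
#' With `baseline_strategy = "fit"` the baselines come from the full
#' two-state fit with co-fitted linear baselines; `"endpoint"` uses
#' straight lines through the first and last three points. Curves
#' already flagged normalized are returned unchanged.
#'
#' @param curve a `denaturation_curve`.
#' @param baseline_strategy `"fit"` (default) or `"endpoint"`.
#' @param temperature_k temperature (K) for the fit-based strategy.
#' @return A normalized `denaturation_curve`; the strategy used is
#'   recorded in `$normalization`.
#' @export
normalize_curve <- function(curve, baseline_strategy = c("fit", "endpoint"),
                            temperature_k = 298) {
  stopifnot(inherits(curve, "denaturation_curve"))
  baseline_strategy <- match.arg(baseline_strategy)
  if (isTRUE(curve$normalized)) return(curve)
  if (diff(range(curve$signal)) < 1e-8)
    stop("no discernible transition: signal is constant")
  d <- curve$axis; y <- curve$signal
  if (baseline_strategy == "fit") {
    fit <- fit_chemical_two_state(curve, temperature_k)
    bf <- fit$baselines$folded; bu <- fit$baselines$unfolded
  } else {
    lo <- seq_len(3); hi <- length(d) - 2:0
    cf <- coef(lm(y[lo] ~ d[lo])); bf <- c(cf[1], cf[2])
    cu <- coef(lm(y[hi] ~ d[hi])); bu <- c(cu[1], cu[2])
  }
  fold <- bf[1] + bf[2] * d
  unf <- bu[1] + bu[2] * d
  if (any(abs(unf - fold) < 1e-10))
    stop("no discernible transition: baselines coincide")
  out <- new_denaturation_curve(d, (y - fold) / (unf - fold),
                                curve$mode, TRUE, truth = curve$truth)
  out$normalization <- baseline_strategy
  out
}

#' Fit a thermal melt to a sigmoid and extract Tm
#'
#' Empirical four-parameter logistic
#' y(T) = a + (b - a) / (1 + exp((tm - T)/width)); the midpoint `tm` is
#' the melting temperature. Input rows are sorted by temperature before
#' fitting, so axis order does not matter.
#'
#' @param curve a `denaturation_curve` in thermal mode (axis in C).
#' @return A `thermal_fit` with `tm`, `width`, `baselines = c(a, b)`,
#'   `se` and `rss`.
#' @examples
#' cv <- gen_thermal_melt(melt_spec(tm = 55, noise_sd = 0.02, seed = 1))
#' fit_thermal_melt(cv)$tm
#' @export
fit_thermal_melt <- function(curve) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (curve$mode != "thermal") stop("curve is not in thermal mode")
  ord <- order(curve$axis)
  tt <- curve$axis[ord]; y <- curve$signal[ord]
  if (length(tt) < 8) stop("need >= 8 points spanning the transition")
  if (diff(range(y)) < 1e-8) stop("no discernible transition")
  tm0 <- tt[which.min(abs(y - (min(y) + max(y)) / 2))]
  fit <- NULL
  for (w0 in c(3, 1, 8)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a + (b - a) / (1 + exp((tm - tt) / w)),
        data = data.frame(tt = tt, y = y),
        start = list(a = min(y), b = max(y), tm = tm0, w = w0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || deviance(cand) < deviance(fit))) fit <- cand
  }
  if (is.null(fit)) stop("thermal sigmoid fit failed to converge")
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  if (cf[["tm"]] < min(tt) || cf[["tm"]] > max(tt))
    warning("fitted Tm outside the data range", call. = FALSE)
  structure(list(tm = cf[["tm"]], width = abs(cf[["w"]]),
                 baselines = c(cf[["a"]], cf[["b"]]),
                 se = c(tm = unname(se["tm"]), width = unname(se["w"])),
                 rss = deviance(fit)),
            class = "thermal_fit")
}

#' Stability difference between two constructs
#'
#' ddG = dG0(a) - dG0(b), with the error combined in quadrature from
#' the two fit standard errors. Both fits must have been performed at
#' the same temperature.
#'
#' @param fit_a,fit_b `two_state_fit` objects (e.g. reference and
#'   tag-conjugated construct).
#' @return List with `ddG` (kcal/mol) and `se`.
#' @export
delta_delta_g <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "two_state_fit"), inherits(fit_b, "two_state_fit"))
  if (!isTRUE(all.equal(fit_a$temperature_k, fit_b$temperature_k)))
    stop("fits were performed at different temperatures")
  list(ddG = fit_a$dG0 - fit_b$dG0,
       se = sqrt(fit_a$se[["dG0"]]^2 + fit_b$se[["dG0"]]^2))
}
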