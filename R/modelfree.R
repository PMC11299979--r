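#' Lipari-Szabo model-free analysis of 15N backbone relaxation
#'
#' @description
#' Backbone amide 15N R1, R2 and heteronuclear NOE are governed by the
#' dipolar interaction with the attached proton and the 15N chemical
#' shift anisotropy, sampled at a handful of spectral frequencies. The
#' model-free spectral density for isotropic tumbling is
#' J(w) = (2/5) \[S^2 tau_m / (1 + (w tau_m)^2)
#'        + (1 - S^2) tau' / (1 + (w tau')^2)\],
#' with 1/tau' = 1/tau_m + 1/tau_e. The order parameter S^2 measures
#' the amplitude of fast internal motion, tau_e its timescale, and a
#' chemical-exchange term Rex adds to R2. Order-parameter differences
#' are converted to conformational entropy with an entropy-meter
#' calibration, so segment-averaged -T dS profiles can be compared
#' between proteins.
#'
#' @name modelfree
NULL

# angular frequencies (rad/s) of the five spectral density arguments
# relevant to the 15N-1H pair at a given 1H field
nmr_frequencies <- function(field_mhz, const = NMR_CONSTANTS) {
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * const$gamma_n / const$gamma_h
  list(wh = wh, wn = wn)
}

#' Model-free spectral density
#'
#' @param w angular frequency (rad/s); vectorized.
#' @param s2 order parameter in \[0, 1\].
#' @param tau_m overall rotational correlation time (s).
#' @param tau_e internal correlation time (s); 0 collapses the second
#'   term.
#' @return J(w) in s/rad.
#' @export
spectral_density <- function(w, s2, tau_m, tau_e = 0) {
  j <- s2 * tau_m / (1 + (w * tau_m)^2)
  if (tau_e > 0) {
    tp <- 1 / (1 / tau_m + 1 / tau_e)
    j <- j + (1 - s2) * tp / (1 + (w * tp)^2)
  }
  0.4 * j
}

#' Predicted R1, R2 and NOE from model-free parameters
#'
#' Standard 15N dipolar + CSA expressions with the model-free spectral
#' density; Rex (s-1) adds to R2 only.
#'
#' @param s2,tau_m,tau_e,rex model-free parameters (tau in s, rex in
#'   s-1).
#' @param field_mhz 1H Larmor frequency (MHz).
#' @param const spin constants, see [NMR_CONSTANTS].
#' @return Named list `r1`, `r2`, `noe`.
#' @export
relaxation_rates <- function(s2, tau_m, tau_e = 0, rex = 0,
                             field_mhz = 600, const = NMR_CONSTANTS) {
  fr <- nmr_frequencies(field_mhz, const)
  wh <- fr$wh; wn <- fr$wn
  d <- const$mu0_4pi * const$hbar * const$gamma_h * const$gamma_n /
    const$r_nh^3
  c2 <- (wn * const$csa)^2 / 3
  jj <- function(w) spectral_density(abs(w), s2, tau_m, tau_e)
  j0 <- jj(0); jn <- jj(wn); jh <- jj(wh)
  jhmn <- jj(wh - wn); jhpn <- jj(wh + wn)
  r1 <- (d^2 / 4) * (jhmn + 3 * jn + 6 * jhpn) + c2 * jn
  r2 <- (d^2 / 8) * (4 * j0 + jhmn + 3 * jn + 6 * jh + 6 * jhpn) +
    (c2 / 6) * (4 * j0 + 3 * jn) + rex
  sigma <- (d^2 / 4) * (6 * jhpn - jhmn)
  noe <- 1 + (const$gamma_h / const$gamma_n) * sigma / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

#' Specification of a synthetic relaxation dataset
#'
#' @param s2_true per-residue order parameters in \[0, 1\].
#' @param tau_m global rotational correlation time (ns).
#' @param tau_e per-residue internal correlation times (ps); scalar
#'   recycled.
#' @param rex per-residue exchange contributions (s-1); scalar
#'   recycled.
#' @param field_mhz 1H Larmor frequency (MHz).
#' @param noise_frac relative Gaussian noise applied to R1, R2 and to
#'   the NOE (absolute, scaled by |NOE|); errors reported at the same
#'   level.
#' @param residues residue identifiers.
#' @param seed RNG seed; one stream per residue.
#' @return A `relax_spec`.
#' @export
relax_spec <- function(s2_true, tau_m = 5, tau_e = 0, rex = 0,
                       field_mhz = 600, noise_frac = 0,
                       residues = seq_along(s2_true), seed = 1L) {
  if (any(s2_true < 0 | s2_true > 1)) spec_error("s2 must be in [0, 1]")
  if (tau_m <= 0) spec_error("tau_m must be > 0")
  if (any(tau_e < 0)) spec_error("tau_e must be >= 0")
  if (any(rex < 0)) spec_error("rex must be >= 0")
  n <- length(s2_true)
  structure(list(s2_true = s2_true, tau_m = tau_m,
                 tau_e = rep_len(tau_e, n), rex = rep_len(rex, n),
                 field_mhz = field_mhz, noise_frac = noise_frac,
                 residues = residues, seed = as.integer(seed)),
            class = "relax_spec")
}

#' Simulate a per-residue R1/R2/NOE dataset
#'
#' Rates are computed from the model-free forward model
#' ([relaxation_rates()]) and perturbed with relative Gaussian noise;
#' reported errors equal the applied noise level (with a tiny floor of
#' 1e-6 relative when noise_frac = 0, so chi-square weights stay
#' finite while still reflecting that the data are exact).
#'
#' @param spec a [relax_spec()].
#' @return A `relaxation_dataset`: data frame (residue, r1, r1_err,
#'   r2, r2_err, noe, noe_err), `field_mhz`, and the ground truth.
#' @export
gen_relaxation <- function(spec) {
  stopifnot(inherits(spec, "relax_spec"))
  n <- length(spec$s2_true)
  rows <- lapply(seq_len(n), function(i) {
    rr <- relaxation_rates(spec$s2_true[i], spec$tau_m * 1e-9,
                           spec$tau_e[i] * 1e-12, spec$rex[i],
                           spec$field_mhz)
    nf <- spec$noise_frac
    err_frac <- if (nf > 0) nf else 1e-6
    r1 <- rr$r1; r2 <- rr$r2; noe <- rr$noe
    if (nf > 0) {
      set.seed(spec$seed + i)
      eps <- rnorm(3)
      r1 <- r1 * (1 + nf * eps[1])
      r2 <- r2 * (1 + nf * eps[2])
      noe <- noe + abs(rr$noe) * nf * eps[3]
    }
    data.frame(residue = spec$residues[i],
               r1 = r1, r1_err = err_frac * rr$r1,
               r2 = r2, r2_err = err_frac * rr$r2,
               noe = noe, noe_err = err_frac * abs(rr$noe))
  })
  structure(list(data = do.call(rbind, rows), field_mhz = spec$field_mhz,
                 truth = spec),
            class = "relaxation_dataset")
}

#' Fit a single-exponential relaxation decay
#'
#' I(tau) = I0 exp(-R tau) on a series of relaxation delays; used for
#' both R1 and R2 experiments. The rate is invariant to scaling of I0.
#'
#' @param intensities peak intensities.
#' @param delays relaxation delays (s), >= 4.
#' @return List with `rate` (s-1) and `se`.
#' @export
fit_rate <- function(intensities, delays) {
  stopifnot(length(intensities) == length(delays), length(delays) >= 4)
  if (coef(lm(intensities ~ delays))[2] >= 0)
    stop("intensities do not decay with the relaxation delay")
  r0 <- -coef(lm(log(pmax(intensities, max(intensities) * 1e-6)) ~ delays))[2]
  fit <- minpack.lm::nlsLM(
    ii ~ i0 * exp(-r * tau),
    data = data.frame(tau = delays, ii = intensities),
    start = list(i0 = max(intensities), r = max(r0, 1e-3)),
    lower = c(i0 = 0, r = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients["r", "Std. Error"],
                 error = function(e) NA_real_)
  list(rate = coef(fit)[["r"]], se = se)
}

#' Heteronuclear NOE from saturated and reference intensities
#'
#' NOE = I_sat / I_ref with relative errors combined in quadrature:
#' err/NOE = sqrt((I_ref_err/I_ref)^2 + (I_sat_err/I_sat)^2).
#'
#' @param i_sat,i_ref intensities with and without 1H saturation.
#' @param i_sat_err,i_ref_err intensity errors (rmsd noise of each
#'   plane).
#' @return List with `noe` and `err`.
#' @examples
#' compute_hetnoe(0.8, 1.0, 0.04, 0.05)
#' @export
compute_hetnoe <- function(i_sat, i_ref, i_sat_err = 0, i_ref_err = 0) {
  if (i_ref == 0) stop("reference intensity is zero")
  noe <- i_sat / i_ref
  err <- abs(noe) * sqrt((i_ref_err / i_ref)^2 + (i_sat_err / i_sat)^2)
  list(noe = noe, err = err)
}

# chi-square of one residue's (R1, R2, NOE) against model predictions
residue_chi2 <- function(par, obs, tau_m, field_mhz) {
  pred <- relaxation_rates(par[["s2"]], tau_m,
                           tau_e = par[["tau_e"]], rex = par[["rex"]],
                           field_mhz = field_mhz)
  sum(((obs$r1 - pred$r1) / obs$r1_err)^2,
      ((obs$r2 - pred$r2) / obs$r2_err)^2,
      ((obs$noe - pred$noe) / obs$noe_err)^2)
}

# fit one residue with a fixed model (free parameter subset).
# Optimization runs in natural units (S2 unitless, tau_e in ps, Rex in
# s-1) so finite-difference gradients are well scaled; multi-start
# L-BFGS-B with a Nelder-Mead polish.
fit_residue_model <- function(obs, tau_m, field_mhz, free) {
  to_seconds <- c(s2 = 1, tau_e = 1e-12, rex = 1)
  full <- function(p) {
    par <- c(s2 = NA, tau_e = 0, rex = 0)
    par[free] <- p * to_seconds[free]
    residue_chi2(as.list(par), obs, tau_m, field_mhz)
  }
  lower <- c(s2 = 0, tau_e = 0, rex = 0)[free]
  upper <- c(s2 = 1, tau_e = 5000, rex = 30)[free]
  starts <- list(c(s2 = 0.85, tau_e = 20, rex = 1)[free],
                 c(s2 = 0.5, tau_e = 300, rex = 5)[free],
                 c(s2 = 0.97, tau_e = 5, rex = 0.2)[free])
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      optim(p0, full, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) return(NULL)
  if (length(free) > 1) {
    pol <- tryCatch(
      optim(best$par, function(p) {
        if (any(p < lower) || any(p > upper)) return(Inf)
        full(p)
      }, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < best$value) best <- pol
  }
  par <- c(s2 = NA, tau_e = 0, rex = 0)
  par[free] <- best$par * to_seconds[free]
  list(par = par, chi2 = best$value, k = length(free))
}

# rigid-rotor R2/R1 ratio as a function of tau_m; inverted numerically
# for the initial tau_m estimate
rigid_r2_r1 <- function(tau_m, field_mhz) {
  rr <- relaxation_rates(1, tau_m, 0, 0, field_mhz)
  rr$r2 / rr$r1
}

#' Estimate the overall tumbling time from R2/R1
#'
#' Uses residues with NOE above a rigidity cutoff, drops the most
#' extreme 10% of R2/R1 ratios (trimmed mean) and inverts the
#' rigid-rotor R2/R1 relation numerically.
#'
#' @param data relaxation data frame (r1, r2, noe columns).
#' @param field_mhz 1H frequency (MHz).
#' @param noe_cutoff rigidity cutoff on the NOE; default 0.65.
#' @return tau_m in seconds.
#' @export
estimate_tau_m <- function(data, field_mhz, noe_cutoff = 0.65) {
  rigid <- data[data$noe > noe_cutoff & data$r1 > 0 & data$r2 > 0, ]
  if (nrow(rigid) == 0) stop("no rigid residues (NOE > cutoff) to estimate tau_m")
  ratio <- mean(rigid$r2 / rigid$r1, trim = 0.1)
  uniroot(function(tm) rigid_r2_r1(tm, field_mhz) - ratio,
          interval = c(0.3e-9, 60e-9), tol = 1e-13)$root
}

#' Lipari-Szabo model-free fit of a relaxation dataset
#'
#' Three stages: (1) the global tumbling time tau_m is estimated from
#' the trimmed R2/R1 ratio of rigid residues (NOE > 0.65) and refined
#' by minimizing the total chi-square over all residues; (2) each
#' residue is fitted with the four standard models
#' M1 (S2), M2 (S2, tau_e), M3 (S2, Rex), M4 (S2, tau_e, Rex) by
#' weighted chi-square minimization; (3) the model is selected by AIC
#' (chi2 + 2k; with a single field each residue has only three
#' observables, so the small-sample AIC correction degenerates and
#' plain AIC is used).
#'
#' @param dataset a `relaxation_dataset` (see [gen_relaxation()] /
#'   [read_relaxation_tsv()]).
#' @param refine_tau_m logical; grid-refine tau_m by global chi-square
#'   (default TRUE).
#' @return A `modelfree_result`: data frame (residue, s2, tau_e_ps,
#'   rex, model, chi2) plus `tau_m_ns`.
#' @export
fit_model_free <- function(dataset, refine_tau_m = TRUE) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  df <- dataset$data
  field <- dataset$field_mhz
  tau_m <- estimate_tau_m(df, field)
  models <- list(M1 = "s2", M2 = c("s2", "tau_e"),
                 M3 = c("s2", "rex"), M4 = c("s2", "tau_e", "rex"))
  fit_all <- function(tm) {
    lapply(seq_len(nrow(df)), function(i) {
      obs <- df[i, ]
      fits <- lapply(models, function(fr) fit_residue_model(obs, tm, field, fr))
      ok <- !vapply(fits, is.null, TRUE)
      if (!any(ok)) return(NULL)
      aic <- vapply(fits[ok], function(f) f$chi2 + 2 * f$k, 0)
      best <- fits[ok][[which.min(aic)]]
      list(residue = obs$residue, par = best$par, chi2 = best$chi2,
           model = names(fits[ok])[which.min(aic)])
    })
  }
  fits <- fit_all(tau_m)
  if (refine_tau_m) {
    # refine tau_m on exchange-free residues only (their chi2 depends
    # cleanly on the tumbling time), keeping each residue's selected
    # model fixed; the bracket is re-centered until the optimum is
    # interior, since the R2/R1 seed can be off by more than 10% when
    # internal motion is widespread
    for (iter in 1:6) {
      models_by_res <- vapply(fits, function(f)
        if (is.null(f)) "" else f$model, "")
      keep <- which(models_by_res %in% c("M1", "M2"))
      if (length(keep) < 3) break
      sub_chi2 <- function(tm) {
        sum(vapply(keep, function(i) {
          f <- fit_residue_model(df[i, ], tm, field, models[[models_by_res[i]]])
          if (is.null(f)) 0 else f$chi2
        }, 0))
      }
      opt <- optimize(sub_chi2, interval = tau_m * c(0.9, 1.1),
                      tol = tau_m * 1e-7)
      moved <- abs(opt$minimum / tau_m - 1)
      tau_m <- opt$minimum
      fits <- fit_all(tau_m)
      if (moved < 0.095) break   # interior optimum: converged
    }
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (any(!ok))
    warning(sum(!ok), " residue(s) failed to converge and were excluded",
            call. = FALSE)
  fits <- fits[ok]
  out <- data.frame(
    residue = vapply(fits, `[[`, df$residue[1], "residue"),
    s2 = vapply(fits, function(f) f$par[["s2"]], 0),
    tau_e_ps = vapply(fits, function(f) f$par[["tau_e"]] * 1e12, 0),
    rex = vapply(fits, function(f) f$par[["rex"]], 0),
    model = vapply(fits, `[[`, "", "model"),
    chi2 = vapply(fits, `[[`, 0, "chi2"))
  structure(list(data = out, tau_m_ns = tau_m * 1e9, field_mhz = field),
            class = "modelfree_result")
}

#' @export
print.modelfree_result <- function(x, ...) {
  cat(sprintf("<modelfree_result> %d residues, tau_m = %.2f ns, mean S2 = %.3f\n",
              nrow(x$data), x$tau_m_ns, mean(x$data$s2)))
  invisible(x)
}

#' Entropy-meter conversion of order parameters
#'
#' Per-residue backbone conformational entropy from S^2 via a
#' configurable monotone map. The default is the linear entropy meter
#' S_conf = s_slope (1 - S^2) + s_0 with a calibration slope of
#' 5 cal mol-1 K-1 per unit (1 - S^2), of the order of published
#' NMR entropy-meter calibrations; all comparisons in this package use
#' entropy differences, so the additive constant s_0 cancels.
#'
#' @param s2 order parameters in \[0, 1\].
#' @param s_slope calibration slope (kcal mol-1 K-1 per unit (1-S^2)).
#' @param s_0 additive constant (kcal mol-1 K-1).
#' @return Entropy per residue (kcal mol-1 K-1).
#' @export
order_param_entropy <- function(s2, s_slope = 5e-3, s_0 = 0) {
  if (any(s2 < 0 | s2 > 1)) stop("S^2 must lie in [0, 1]")
  s_slope * (1 - s2) + s_0
}

#' Segment-averaged conformational entropy comparison
#'
#' Converts both proteins' order parameters to entropies, averages per
#' segment, and reports -T dS per segment with
#' dS = S_conf(reference) - S_conf(query): positive -T dS means the
#' query is more flexible than the reference. Errors are quadrature
#' sums of segment SEMs (scaled by T); segments exceeding
#' (mean + error) are flagged. Antisymmetric under swapping inputs.
#'
#' @param res_a,res_b `modelfree_result` objects (reference, query) or
#'   data frames with residue and s2 columns.
#' @param map segment map, see [ubiquitin_segments()].
#' @param temperature_k temperature (K).
#' @param ... passed to [order_param_entropy()].
#' @return Data frame (segment, minus_t_ds, err, flag).
#' @export
segment_entropy_compare <- function(res_a, res_b, map = ubiquitin_segments(),
                                    temperature_k = 298, ...) {
  get_df <- function(x) if (inherits(x, "modelfree_result")) x$data else x
  a <- get_df(res_a); b <- get_df(res_b)
  sa <- order_param_entropy(a$s2, ...)
  sb <- order_param_entropy(b$s2, ...)
  rows <- lapply(names(map), function(seg) {
    ia <- a$residue %in% map[[seg]]; ib <- b$residue %in% map[[seg]]
    if (!any(ia) || !any(ib)) return(NULL)
    ds <- mean(sa[ia]) - mean(sb[ib])
    sem_a <- if (sum(ia) > 1) sd(sa[ia]) / sqrt(sum(ia)) else 0
    sem_b <- if (sum(ib) > 1) sd(sb[ib]) / sqrt(sum(ib)) else 0
    data.frame(segment = seg,
               minus_t_ds = -temperature_k * ds,
               err = temperature_k * sqrt(sem_a^2 + sem_b^2))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out$flag <- out$minus_t_ds > mean(out$minus_t_ds) + out$err
  out
}
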