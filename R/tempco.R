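#' Amide temperature coefficients
#'
#' @description
#' The temperature coefficient of a backbone amide proton,
#' Tc = d(delta_NH)/dT in ppb/K, reports on hydrogen bonding: values
#' much more negative than the protein mean indicate weak or absent
#' hydrogen bonds and local disorder propensity. Because low-identity
#' proteins cannot be compared residue by residue, coefficients are
#' averaged over secondary-structure segments and compared segment-wise
#' (delta Tc_avg = mean(reference) - mean(query)).
#'
#' @name tempco
NULL

#' Specification of a synthetic amide-shift temperature series
#'
#' @param residues residue identifiers (integer).
#' @param tc_true per-residue temperature coefficients (ppb/K,
#'   typically negative).
#' @param intercepts shift at the reference temperature (ppm); default
#'   8.3 ppm for all residues.
#' @param temperatures measurement temperatures (K), strictly
#'   increasing, >= 3 values; default 283-313 K in 5 K steps.
#' @param t_ref reference temperature for the intercepts (K); default
#'   283 K, the lowest acquisition temperature.
#' @param noise_sd shift noise (ppm).
#' @param seed RNG seed. One stream per residue (seed + residue index)
#'   so adding residues does not reshuffle earlier draws.
#' @return A `tempco_spec`.
#' @export
tempco_spec <- function(residues, tc_true, intercepts = NULL,
                        temperatures = seq(283, 313, by = 5),
                        t_ref = 283, noise_sd = 0, seed = 1L) {
  stopifnot(length(residues) == length(tc_true))
  if (length(temperatures) < 3) spec_error("need >= 3 temperatures")
  if (any(diff(temperatures) <= 0))
    spec_error("temperatures must be strictly increasing")
  if (is.null(intercepts)) intercepts <- rep(8.3, length(residues))
  structure(list(residues = residues, tc_true = tc_true,
                 intercepts = intercepts, temperatures = temperatures,
                 t_ref = t_ref, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tempco_spec")
}

#' Simulate an amide-shift table across temperatures
#'
#' delta(T) = intercept + Tc (T - T_ref) 1e-3 ppm + noise, per residue
#' (Tc in ppb/K, shifts in ppm).
#'
#' @param spec a [tempco_spec()].
#' @return A `shift_table`: long-format data frame (residue,
#'   temperature_K, shift_ppm) with the ground truth attached.
#' @export
gen_shift_table <- function(spec) {
  stopifnot(inherits(spec, "tempco_spec"))
  rows <- do.call(rbind, lapply(seq_along(spec$residues), function(i) {
    shifts <- spec$intercepts[i] +
      spec$tc_true[i] * (spec$temperatures - spec$t_ref) * 1e-3
    if (spec$noise_sd > 0) {
      set.seed(spec$seed + i)
      shifts <- shifts + rnorm(length(shifts), 0, spec$noise_sd)
    }
    data.frame(residue = spec$residues[i],
               temperature_K = spec$temperatures,
               shift_ppm = shifts)
  }))
  structure(list(data = rows, truth = spec), class = "shift_table")
}

#' Per-residue temperature-coefficient regression
#'
#' Ordinary least squares of the amide 1H shift against temperature for
#' every residue with at least 3 points. Slopes are reported in ppb/K
#' (ppm inputs are scaled on output) together with the intercept, the
#' slope standard error and the residual sum of squares
#' RSS = sum_i (y_i - f(x_i))^2.
#'
#' @param table a `shift_table` or a long-format data frame with
#'   columns residue, temperature_K, shift_ppm.
#' @return Data frame (residue, tc, intercept, se_tc, rss, n); residues
#'   with fewer than 3 temperatures are skipped with a warning.
#' @examples
#' tab <- data.frame(residue = 1, temperature_K = c(283, 293, 303),
#'                   shift_ppm = c(8.50, 8.45, 8.40))
#' fit_temp_coefficients(tab)$tc  # -5 ppb/K
#' @export
fit_temp_coefficients <- function(table) {
  df <- if (inherits(table, "shift_table")) table$data else table
  stopifnot(all(c("residue", "temperature_K", "shift_ppm") %in% names(df)))
  if (any(!is.finite(df$shift_ppm))) {
    df <- df[is.finite(df$shift_ppm), ]
  }
  res <- lapply(split(df, df$residue), function(sub) {
    if (nrow(sub) < 3) return(NULL)
    fit <- lm(shift_ppm ~ temperature_K, data = sub)
    sm <- suppressWarnings(summary(fit))$coefficients
    data.frame(residue = sub$residue[1],
               tc = coef(fit)[[2]] * 1e3,     # ppm/K -> ppb/K
               intercept = coef(fit)[[1]],
               se_tc = sm[2, "Std. Error"] * 1e3,
               rss = sum(residuals(fit)^2),
               n = nrow(sub))
  })
  skipped <- vapply(res, is.null, TRUE)
  if (any(skipped))
    warning(sum(skipped), " residue(s) skipped (< 3 temperatures)",
            call. = FALSE)
  out <- do.call(rbind, res[!skipped])
  rownames(out) <- NULL
  out[order(out$residue), , drop = FALSE]
}

#' Flag disorder-prone residues from temperature coefficients
#'
#' Residues with Tc more negative than (mean - SD) across the protein
#' are flagged as weak-hydrogen-bond / disorder-prone. The rule assumes
#' the conventional negative mean Tc of folded amides; a positive mean
#' indicates a sign-convention problem and raises an error. With zero
#' spread no residue is flagged.
#'
#' @param results output of [fit_temp_coefficients()].
#' @return Integer vector of flagged residue identifiers (possibly
#'   empty), with the threshold in attribute `"threshold"`.
#' @export
flag_disordered <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 5)
  mu <- mean(results$tc)
  if (mu > 0)
    stop("mean Tc is positive; amide coefficients are expected negative ",
         "(check the sign convention of the input)")
  thr <- mu - sd(results$tc)
  out <- results$residue[results$tc < thr]
  attr(out, "threshold") <- thr
  out
}

#' Segment-averaged temperature coefficients
#'
#' Arithmetic mean and standard error of the mean per named
#' secondary-structure segment. Singleton segments have undefined SEM
#' and are flagged; empty segments are dropped with a warning;
#' unassigned residues are reported in the `"unassigned"` attribute.
#'
#' @param results output of [fit_temp_coefficients()].
#' @param map named list of residue ranges (see
#'   [ubiquitin_segments()]).
#' @return Data frame (segment, mean, sem, n).
#' @export
segment_average <- function(results, map = ubiquitin_segments()) {
  stopifnot(is.data.frame(results))
  rows <- lapply(names(map), function(seg) {
    vals <- results$tc[results$residue %in% map[[seg]]]
    if (length(vals) == 0) return(NULL)
    data.frame(segment = seg, mean = mean(vals),
               sem = if (length(vals) > 1) sd(vals) / sqrt(length(vals))
                     else NA_real_,
               n = length(vals))
  })
  empty <- vapply(rows, is.null, TRUE)
  if (any(empty))
    warning("empty segment(s) dropped: ",
            paste(names(map)[empty], collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  assigned <- unlist(map, use.names = FALSE)
  attr(out, "unassigned") <- setdiff(results$residue, assigned)
  out
}

#' Segment-wise comparison of two proteins
#'
#' delta = mean(reference) - mean(query) per shared segment, with the
#' error combined in quadrature from the two SEMs. Segments whose delta
#' exceeds (mean of deltas + quadrature error) are flagged, mirroring
#' the highlighting convention used for segment plots. Antisymmetric:
#' swapping the inputs negates every delta.
#'
#' @param seg_a,seg_b outputs of [segment_average()] for the reference
#'   and query protein.
#' @return Data frame (segment, mean_a, mean_b, delta, err, flag).
#' @export
compare_proteins <- function(seg_a, seg_b) {
  shared <- intersect(seg_a$segment, seg_b$segment)
  if (length(shared) == 0) stop("no shared segments between the two proteins")
  a <- seg_a[match(shared, seg_a$segment), ]
  b <- seg_b[match(shared, seg_b$segment), ]
  delta <- a$mean - b$mean
  err <- sqrt(ifelse(is.na(a$sem), 0, a$sem)^2 +
              ifelse(is.na(b$sem), 0, b$sem)^2)
  thr <- mean(delta) + err
  data.frame(segment = shared, mean_a = a$mean, mean_b = b$mean,
             delta = delta, err = err, flag = delta > thr)
}
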