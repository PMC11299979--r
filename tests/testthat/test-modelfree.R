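test_that("relaxation-rate fits are exact on the standard delay grid", {
  delays <- c(0.004, 0.03, 0.06, 0.1, 0.15, 0.2, 0.4, 0.8)
  ii <- exp(-1.5 * delays)
  expect_equal(fit_rate(ii, delays)$rate, 1.5, tolerance = 1e-8)
  # scale invariance in I0
  expect_equal(fit_rate(10 * ii, delays)$rate, 1.5, tolerance = 1e-8)
  expect_error(fit_rate(rev(ii), rev(-delays + 1)), "decay")
})

test_that("noisy rate estimates carry < 2% bias", {
  delays <- c(0.004, 0.03, 0.06, 0.1, 0.15, 0.2, 0.4, 0.8)
  rates <- vapply(1:50, function(sd) {
    set.seed(200 + sd)
    fit_rate(exp(-1.5 * delays) + rnorm(8, 0, 0.05 * 1), delays)$rate
  }, 0)
  expect_lt(abs(mean(rates) - 1.5) / 1.5, 0.02)
})

test_that("hetNOE ratio and error propagation match the hand-coded formula", {
  r <- compute_hetnoe(0.8, 1.0, 0.04, 0.05)
  expect_equal(r$noe, 0.8, tolerance = 1e-12)
  expect_equal(r$err, 0.8 * sqrt(0.0016 / 0.64 + 0.0025 / 1.0),
               tolerance = 1e-12)
  expect_equal(r$err, 0.0566, tolerance = 1e-3)
  expect_equal(compute_hetnoe(1, 1)$noe, 1)
  expect_equal(compute_hetnoe(0.9, 1.2)$err, 0)
  expect_error(compute_hetnoe(0.8, 0), "zero")
})

test_that("rigid residues refit as the pure-S2 model at zero noise", {
  ds <- gen_relaxation(relax_spec(rep(1, 6), tau_m = 5, tau_e = 0, rex = 0,
                                  field_mhz = 600, noise_frac = 0))
  mf <- fit_model_free(ds)
  expect_equal(mf$data$s2, rep(1, 6), tolerance = 1e-3)
  expect_true(all(mf$data$model == "M1"))
  expect_equal(mf$tau_m_ns, 5, tolerance = 1e-4)
})

test_that("model-free roundtrip is exact at zero noise across models", {
  s2 <- c(rep(0.87, 8), 0.6, 0.85)
  te <- c(rep(20, 8), 300, 50)
  rex <- c(rep(0, 9), 3)
  ds <- gen_relaxation(relax_spec(s2, tau_m = 5, tau_e = te, rex = rex,
                                  field_mhz = 600, noise_frac = 0))
  mf <- fit_model_free(ds)
  expect_equal(mf$tau_m_ns, 5, tolerance = 1e-6)
  expect_equal(mf$data$s2, s2, tolerance = 1e-6)
  expect_equal(mf$data$tau_e_ps, te, tolerance = 1e-5)
  expect_equal(mf$data$rex[10], 3, tolerance = 1e-5)
  # chi2 at the fit cannot exceed chi2 at the truth (optimizer sanity)
  for (i in c(1, 9, 10)) {
    chi_true <- tagfold:::residue_chi2(
      list(s2 = s2[i], tau_e = te[i] * 1e-12, rex = rex[i]),
      ds$data[i, ], 5e-9, 600)
    expect_lte(mf$data$chi2[i], chi_true + 1e-3)
  }
})

test_that("an exchange contribution forces selection of an Rex model", {
  ds <- gen_relaxation(relax_spec(c(0.85, 0.85), tau_m = 5, tau_e = c(0, 0),
                                  rex = c(0, 3), noise_frac = 0))
  mf <- fit_model_free(ds)
  expect_false(grepl("3|4", mf$data$model[1]))
  expect_true(mf$data$model[2] %in% c("M3", "M4"))
  expect_equal(mf$data$rex[2], 3, tolerance = 0.2 * 3)
})

test_that("entropy map is monotone and bounded", {
  expect_equal(order_param_entropy(1), 0)
  s <- order_param_entropy(c(0.9, 0.7))
  expect_gt(s[2], s[1])
  expect_error(order_param_entropy(1.2), "0, 1")
  # equal order parameters give zero entropy difference everywhere
  expect_equal(order_param_entropy(c(0.8, 0.9)) -
                 order_param_entropy(c(0.8, 0.9)), c(0, 0))
})

test_that("segment entropy comparison is antisymmetric with uniform shifts equal", {
  set.seed(12)
  res_a <- data.frame(residue = 1:71, s2 = runif(71, 0.8, 0.95))
  res_b <- res_a; res_b$s2 <- res_a$s2 - 0.1
  cmp <- segment_entropy_compare(res_a, res_b)
  # uniform S2 drop: equal -TdS in every segment, all positive
  expect_equal(diff(range(cmp$minus_t_ds)), 0, tolerance = 1e-10)
  expect_true(all(cmp$minus_t_ds > 0))
  swapped <- segment_entropy_compare(res_b, res_a)
  expect_equal(swapped$minus_t_ds, -cmp$minus_t_ds, tolerance = 1e-12)
  ident <- segment_entropy_compare(res_a, res_a)
  expect_true(all(ident$minus_t_ds == 0))
})

test_that("flexibility confined to one helix is the only flagged segment", {
  set.seed(13)
  res_a <- data.frame(residue = 1:71, s2 = runif(71, 0.85, 0.92))
  res_b <- res_a
  in_a1 <- res_b$residue %in% 23:34
  res_b$s2[in_a1] <- res_b$s2[in_a1] - 0.25
  cmp <- segment_entropy_compare(res_a, res_b)
  expect_true(cmp$flag[cmp$segment == "alpha1"])
  expect_false(any(cmp$flag[cmp$segment != "alpha1"]))
})
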