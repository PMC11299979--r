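test_that("chemical melt generator obeys the two-state midpoint identities", {
  cv <- gen_chemical_melt(melt_spec(dG0 = 5, m_value = 2, noise_sd = 0,
                                    axis = seq(0, 6, by = 0.25)))
  # midpoint Cm = dG0/m = 2.5 M: populations equal there
  expect_equal(cv$signal[cv$axis == 2.5], 0.5, tolerance = 1e-12)
  # dG([D]) = dG0 - m [D] = 0 at [D] = 4 for dG0 = 8, m = 2
  cv2 <- gen_chemical_melt(melt_spec(dG0 = 8, m_value = 2, noise_sd = 0,
                                     axis = seq(0, 6, by = 0.5)))
  expect_equal(cv2$signal[cv2$axis == 4], 0.5, tolerance = 1e-12)
})

test_that("thermal melt generator has its midpoint at tm and a step limit", {
  tv <- gen_thermal_melt(melt_spec(tm = 70, noise_sd = 0))
  expect_equal(tv$signal[tv$axis == 70], 0.5, tolerance = 1e-12)
  step <- gen_thermal_melt(melt_spec(tm = 55.5, slope_t = 0, noise_sd = 0))
  expect_true(all(step$signal %in% c(0, 1)))
  expect_equal(step$signal[step$axis >= 55.5][1], 1)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_chemical_melt(melt_spec(dG0 = 3, m_value = 1.5, noise_sd = 0.02, seed = 11))
  b <- gen_chemical_melt(melt_spec(dG0 = 3, m_value = 1.5, noise_sd = 0.02, seed = 11))
  expect_identical(a$signal, b$signal)
  p1 <- gen_proteolysis(proteolysis_spec(kop = 1e-5, noise_sd = 0.03, seed = 4))
  p2 <- gen_proteolysis(proteolysis_spec(kop = 1e-5, noise_sd = 0.03, seed = 4))
  expect_identical(p1$data$intensity, p2$data$intensity)
  t1 <- gen_toy_trajectory(toy_trajectory_spec(fluct_amplitudes = 0.4,
                                               n_frames = 3, seed = 9))
  t2 <- gen_toy_trajectory(toy_trajectory_spec(fluct_amplitudes = 0.4,
                                               n_frames = 3, seed = 9))
  expect_identical(t1$frames, t2$frames)
})

test_that("per-residue noise streams do not reshuffle when residues are added", {
  small <- gen_shift_table(tempco_spec(1:5, rep(-5, 5), noise_sd = 0.002, seed = 3))
  large <- gen_shift_table(tempco_spec(1:8, rep(-5, 8), noise_sd = 0.002, seed = 3))
  expect_identical(small$data$shift_ppm,
                   large$data$shift_ppm[large$data$residue %in% 1:5])
})

test_that("proteolysis generator satisfies the exponential identity", {
  # kop * kcat_km * c = 0.01 s^-1  =>  I(100 s) = exp(-1)
  sp <- proteolysis_spec(kop = 1e-4, kcat_km = 1e4, concentrations = 0.01,
                         times = c(0, 50, 100, 200), noise_sd = 0)
  ds <- gen_proteolysis(sp)
  expect_equal(ds$data$intensity[ds$data$time == 100], exp(-1),
               tolerance = 1e-12)
  expect_true(all(ds$control$intensity == 1))
})

test_that("shift-table generator is exactly invertible at zero noise", {
  sp <- tempco_spec(1:6, tc_true = c(-5, -7.2, -3, -9, -4.4, -6),
                    noise_sd = 0)
  fit <- fit_temp_coefficients(gen_shift_table(sp))
  expect_equal(fit$tc, sp$tc_true, tolerance = 1e-9)
  expect_true(all(fit$rss < 1e-24))
})

test_that("relaxation generator matches the independent textbook evaluation", {
  # frozen values from a direct, separate evaluation of the dipolar+CSA
  # relaxation expressions with the model-free spectral density
  rr <- relaxation_rates(0.85, 5e-9, 50e-12, 0, 600)
  expect_equal(rr$r1, 1.973265683, tolerance = 1e-8)
  expect_equal(rr$r2, 6.860185005, tolerance = 1e-8)
  expect_equal(rr$noe, 0.7012430742, tolerance = 1e-8)
  rr2 <- relaxation_rates(0.6, 8e-9, 200e-12, 3, 800)
  expect_equal(rr2$r1, 1.023988359, tolerance = 1e-8)
  expect_equal(rr2$r2, 11.53584876, tolerance = 1e-8)
  expect_equal(rr2$noe, -0.2378444476, tolerance = 1e-7)
})

test_that("rigid-rotor limit collapses the spectral density and rates", {
  tau_m <- 5e-9
  w <- c(0, 2 * pi * 600e6 * c(0.1, 0.9, 1, 1.1))
  expect_equal(spectral_density(w, 1, tau_m, 0),
               0.4 * tau_m / (1 + (w * tau_m)^2), tolerance = 1e-14)
  # tau_e = 0 removes the internal-motion branch even when S2 < 1
  expect_equal(spectral_density(1e9, 0.8, tau_m, 0),
               0.4 * 0.8 * tau_m / (1 + (1e9 * tau_m)^2), tolerance = 1e-14)
  rigid <- relaxation_rates(1, tau_m, 0, 0, 600)
  expect_equal(rigid$r1, 2.272635932, tolerance = 1e-8)
  expect_equal(rigid$r2, 8.021217161, tolerance = 1e-8)
})

test_that("toy trajectory honors zero fluctuations and the RMSF limit", {
  tr <- toy_static(n_frames = 3)
  for (f in seq_along(tr$frames))
    expect_identical(tr$frames[[f]], tr$reference)
  # sigma = 0.5 A isotropic => RMSF -> sigma * sqrt(3) (superposition
  # absorbs a small share of the variance)
  tr2 <- gen_toy_trajectory(toy_trajectory_spec(fluct_amplitudes = 0.5,
                                                n_frames = 400, seed = 2))
  rmsf <- rmsf_rmsd(tr2)$rmsf
  expect_equal(mean(rmsf), 0.5 * sqrt(3), tolerance = 0.08)
})

test_that("spec validation rejects non-physical parameters", {
  expect_error(melt_spec(dG0 = -1, m_value = 2), "dG0")
  expect_error(melt_spec(dG0 = 2, m_value = 2, axis = c(1, 1, 2)), "increasing")
  expect_error(gen_thermal_melt(melt_spec(tm = 150)), "axis")
  expect_error(proteolysis_spec(kop = 0), "kop")
  expect_error(relax_spec(1.2), "s2")
  expect_error(tempco_spec(1, -5, temperatures = c(283, 293)), "3 temperatures")
  expect_error(toy_trajectory_spec(unfold_schedule = c(0.5, 0.8, 1),
                                   n_frames = 3), "non-increasing")
})
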