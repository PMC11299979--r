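test_that("exact collinear shifts give the exact slope and zero RSS", {
  tab <- data.frame(residue = 1, temperature_K = c(283, 293, 303),
                    shift_ppm = c(8.50, 8.45, 8.40))
  fit <- fit_temp_coefficients(tab)
  expect_equal(fit$tc, -5, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-28)
  const <- data.frame(residue = 2, temperature_K = c(283, 293, 303),
                      shift_ppm = rep(8.2, 3))
  expect_equal(fit_temp_coefficients(const)$tc, 0, tolerance = 1e-12)
})

test_that("noisy slopes equal the closed-form OLS solution", {
  sp <- tempco_spec(1:8, tc_true = runif(8, -10, -2), noise_sd = 0.002,
                    seed = 5, temperatures = seq(283, 313, by = 5))
  st <- gen_shift_table(sp)
  fit <- fit_temp_coefficients(st)
  for (r in 1:8) {
    sub <- st$data[st$data$residue == r, ]
    ols <- oracle_ols(sub$temperature_K, sub$shift_ppm)
    expect_equal(fit$tc[fit$residue == r], unname(ols["slope"]) * 1e3,
                 tolerance = 1e-9)
  }
  # estimates are invariant to centering the temperature axis
  shifted <- st$data
  shifted$temperature_K <- shifted$temperature_K - 298
  expect_equal(fit_temp_coefficients(shifted)$tc, fit$tc, tolerance = 1e-9)
})

test_that("residues with too few temperatures are skipped with a warning", {
  tab <- rbind(
    data.frame(residue = 1, temperature_K = c(283, 293, 303),
               shift_ppm = c(8.5, 8.45, 8.4)),
    data.frame(residue = 2, temperature_K = c(283, 293), shift_ppm = c(8, 8)))
  expect_warning(fit <- fit_temp_coefficients(tab), "skipped")
  expect_equal(fit$residue, 1)
})

test_that("disorder flagging applies the mean-minus-SD rule", {
  res <- data.frame(residue = 1:5, tc = c(-4, -4, -4, -4, -12))
  flagged <- flag_disordered(res)
  expect_equal(as.integer(flagged), 5L)
  # equal coefficients: zero SD, nothing flagged
  eq <- data.frame(residue = 1:5, tc = rep(-5, 5))
  expect_length(flag_disordered(eq), 0)
  # a positive mean indicates a flipped sign convention
  pos <- data.frame(residue = 1:5, tc = c(4, 4, 4, 4, 12))
  expect_error(flag_disordered(pos), "sign")
})

test_that("segment averages reproduce the pooled-mean identity", {
  res <- data.frame(residue = 1:71, tc = rnorm(71, -6, 2))
  seg <- segment_average(res, ubiquitin_segments())
  expect_equal(seg$mean[seg$segment == "beta1"],
               mean(res$tc[res$residue %in% 2:7]), tolerance = 1e-12)
  # size-weighted mean of segment means equals the mean over assigned residues
  assigned <- unlist(ubiquitin_segments())
  expect_equal(sum(seg$mean * seg$n) / sum(seg$n),
               mean(res$tc[res$residue %in% assigned]), tolerance = 1e-12)
  expect_true(all(attr(seg, "unassigned") %in% setdiff(1:71, assigned)))
  # singleton segment: mean = value, sem undefined
  one <- segment_average(res[res$residue == 48, , drop = FALSE],
                         list(beta4 = 48:50))
  expect_equal(one$mean, res$tc[res$residue == 48])
  expect_true(is.na(one$sem))
})

test_that("cross-protein comparison is antisymmetric and translation-aware", {
  set.seed(8)
  res_a <- data.frame(residue = 1:71, tc = rnorm(71, -6, 1.5))
  res_b <- res_a; res_b$tc <- res_a$tc - 2     # uniformly weaker hbonds
  seg_a <- segment_average(res_a)
  seg_b <- segment_average(res_b)
  cmp <- compare_proteins(seg_a, seg_b)
  expect_equal(cmp$delta, rep(2, nrow(cmp)), tolerance = 1e-12)
  swapped <- compare_proteins(seg_b, seg_a)
  expect_equal(swapped$delta, -cmp$delta, tolerance = 1e-12)
  ident <- compare_proteins(seg_a, seg_a)
  expect_true(all(ident$delta == 0))
  expect_false(any(ident$flag))
})

test_that("a segment with deliberately weakened hydrogen bonds is flagged", {
  # query built so beta1+beta2 coefficients are far more negative
  set.seed(9)
  res_ref <- data.frame(residue = 1:71, tc = rnorm(71, -5, 0.3))
  res_query <- res_ref
  weak <- res_query$residue %in% c(2:7, 11:17)
  res_query$tc[weak] <- res_query$tc[weak] - 4
  cmp <- compare_proteins(segment_average(res_ref), segment_average(res_query))
  expect_true(all(cmp$flag[cmp$segment %in% c("beta1", "beta2")]))
  expect_false(any(cmp$flag[!cmp$segment %in% c("beta1", "beta2")]))
})
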