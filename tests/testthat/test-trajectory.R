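test_that("native contacts match the exhaustive pair scan and separation rule", {
  tr <- toy_static()
  cc <- define_native_contacts(tr)
  oc <- oracle_contacts(tr)
  got <- paste(cc$i, cc$j)
  want <- paste(oc[, 1], oc[, 2])
  expect_setequal(got, want)
  expect_true(all(abs(cc$i - cc$j) >= 4))
  # tightening the separation rule drops the near-diagonal pairs
  cc8 <- define_native_contacts(tr, min_separation = 8)
  expect_true(all(abs(cc8$i - cc8$j) >= 8))
})

test_that("alpha is 1 on native frames and follows a breaking schedule", {
  tr <- toy_static(n_frames = 3)
  cc <- define_native_contacts(tr)
  expect_equal(contact_fraction(tr, cc), rep(1, 3))
  sch <- seq(1, 0.5, length.out = 15)
  tr2 <- gen_toy_trajectory(toy_trajectory_spec(n_residues = 20,
                                                unfold_schedule = sch,
                                                n_frames = 15, seed = 3))
  cc2 <- define_native_contacts(tr2)
  a <- contact_fraction(tr2, cc2)
  expect_true(all(diff(a) <= 1e-9))            # monotone under the schedule
  expect_equal(a, tr2$truth$alpha_true, tolerance = 1e-12)
  expect_equal(a[15], 0.5, tolerance = 0.1)    # residue granularity
})

test_that("eta counts native backbone hydrogen bonds per strand pair", {
  tr <- toy_static(n_frames = 2)
  sp <- list(b1b2 = list(a = 1:8, b = 9:16))
  eta <- hbond_fraction(tr, sp)
  expect_equal(as.numeric(eta), rep(1, 2))
  # pull the second strand away gradually: eta monotone non-increasing
  # and equal to the hand-counted fraction of intact N...O pairs
  tr2 <- tr
  tr2$frames <- lapply(1:4, function(f) {
    m <- tr$reference
    idx <- tr$topology$residue %in% 9:16
    m[idx, 2] <- m[idx, 2] + (f - 1) * 0.6
    m
  })
  eta2 <- as.numeric(hbond_fraction(tr2, sp))
  expect_true(all(diff(eta2) <= 1e-9))
  n_at <- which(tr$topology$atom == "N")
  o_at <- which(tr$topology$atom == "O")
  hand <- vapply(tr2$frames, function(m) {
    kept <- 0; total <- 0
    for (d in n_at) for (a in o_at) {
      rd <- tr$topology$residue[d]; ra <- tr$topology$residue[a]
      if (rd %in% 1:8 && ra %in% 9:16 || rd %in% 9:16 && ra %in% 1:8) {
        ref_d <- sqrt(sum((tr$reference[d, ] - tr$reference[a, ])^2))
        if (ref_d <= 3.5) {
          total <- total + 1
          if (sqrt(sum((m[d, ] - m[a, ])^2)) <= 3.5) kept <- kept + 1
        }
      }
    }
    kept / total
  }, 0)
  expect_equal(eta2, hand, tolerance = 1e-12)
})

test_that("RMSD/RMSF vanish for static or rigidly rotated trajectories", {
  tr <- toy_static(n_frames = 4)
  rr <- rmsf_rmsd(tr)
  expect_equal(rr$rmsd, rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(rr$rmsf), rep(0, 20), tolerance = 1e-10)
  rot <- rotate_traj(tr)
  rr_rot <- rmsf_rmsd(rot)
  expect_equal(rr_rot$rmsd, rep(0, 4), tolerance = 1e-8)
})

test_that("all distance metrics are invariant under global rototranslation", {
  tr <- gen_toy_trajectory(toy_trajectory_spec(n_residues = 20,
                                               fluct_amplitudes = 0.3,
                                               n_frames = 6, seed = 6))
  rot <- rotate_traj(tr)
  cc <- define_native_contacts(tr)
  expect_equal(contact_fraction(rot, cc), contact_fraction(tr, cc),
               tolerance = 1e-9)
  sp <- list(b1b2 = list(a = 1:8, b = 9:16))
  expect_equal(as.numeric(hbond_fraction(rot, sp)),
               as.numeric(hbond_fraction(tr, sp)), tolerance = 1e-9)
  expect_equal(gyration(rot)$rog, gyration(tr)$rog, tolerance = 1e-9)
  expect_equal(rmsf_rmsd(rot)$rmsd, rmsf_rmsd(tr)$rmsd, tolerance = 1e-8)
})

test_that("gyration matches closed forms and the brute-force formula", {
  tr <- toy_static(n_frames = 1)
  # single atom -> 0; two equal masses 2 A apart -> 1 A
  one <- tr; one$topology <- tr$topology[1, ]; one$reference <- tr$reference[1, , drop = FALSE]
  one$frames <- list(one$reference)
  expect_equal(gyration(one)$rog, 0)
  two <- tr
  two$topology <- data.frame(atom = c("CA", "CA"), residue = 1:2,
                             chain = "A", mass = c(12, 12))
  two$frames <- list(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(gyration(two)$rog, 1, tolerance = 1e-12)
  set.seed(14)
  cloud <- tr
  cloud$topology <- data.frame(atom = "CA", residue = 1:100, chain = "A",
                               mass = runif(100, 10, 20))
  cloud$frames <- list(matrix(rnorm(300), 100, 3))
  expect_equal(gyration(cloud)$rog[1],
               oracle_rg(cloud$frames[[1]], cloud$topology$mass),
               tolerance = 1e-12)
  # loop exclusion acts on rgyr only
  g <- gyration(tr, loop_mask = 17:20)
  expect_false(isTRUE(all.equal(g$rgyr, g$rog)))
})

test_that("free-energy landscape obeys the Boltzmann identities", {
  x <- c(rep(1, 90), rep(2, 10)); y <- x
  fel <- fel_2d(x, y, temperature_k = 300, bins = 2)
  dg <- fel$dg[!is.na(fel$dg)]
  expect_equal(min(dg), 0)
  expect_equal(max(dg), 1.987e-3 * 300 * log(9), tolerance = 1e-12)
  # empty bins masked as NA, never zero
  expect_true(any(is.na(fel$dg)))
  # a bin with N0/e population sits exactly kBT above the minimum
  xe <- c(rep(1, 272), rep(2, 100))
  fe <- fel_2d(xe, xe, temperature_k = 300, bins = 2)
  expect_equal(max(fe$dg, na.rm = TRUE), 1.987e-3 * 300 * log(2.72),
               tolerance = 1e-12)
})

test_that("PCA finds a planted one-dimensional motion and orders variances", {
  tr <- toy_static(n_frames = 24)
  # oscillate residue 5 CA along x
  ca5 <- which(tr$topology$residue == 5 & tr$topology$atom == "CA")
  tr$frames <- lapply(1:24, function(f) {
    m <- tr$reference
    m[ca5, 1] <- m[ca5, 1] + 1.5 * sin(f)
    m
  })
  p <- suppressWarnings(traj_pca(tr))
  expect_true(all(diff(p$variances) <= 1e-12))
  expect_gt(p$variances[1] / sum(p$variances), 0.99)
  # PC1 loads on the oscillating x coordinate
  load_idx <- which.max(abs(p$components[, 1]))
  ca_order <- which(tr$topology$atom == "CA")
  expect_equal(load_idx, (match(ca5, ca_order) - 1) * 3 + 1)
  # variances sum to total positional variance of fitted coordinates
  static <- toy_static(n_frames = 5)
  expect_equal(sum(suppressWarnings(traj_pca(static))$variances), 0, tolerance = 1e-12)
  interp <- pc1_interpolation(p, n = 5)
  expect_length(interp, 5)
  expect_equal(dim(interp[[1]]), c(20, 3))
})

test_that("unfolding schedule reproduces the qualitative plasticity signature", {
  sch <- seq(1, 0.4, length.out = 20)
  tr <- gen_toy_trajectory(toy_trajectory_spec(n_residues = 20,
                                               unfold_schedule = sch,
                                               n_frames = 20, seed = 21))
  cc <- define_native_contacts(tr)
  a <- contact_fraction(tr, cc)
  g <- gyration(tr)$rog
  r <- rmsf_rmsd(tr)$rmsd
  expect_lt(a[20], a[1])
  expect_gt(g[20], g[1])
  expect_gt(r[20], r[1])
  eta <- as.numeric(hbond_fraction(tr, list(b1b2 = list(a = 1:8, b = 9:16))))
  expect_lte(eta[20], eta[1])
})

test_that("disruption and tag occupancy co-localize when forced by design", {
  free <- gen_toy_trajectory(toy_trajectory_spec(fluct_amplitudes = 0.2,
                                                 n_frames = 30, seed = 4))
  cd0 <- contact_disruption(free, free)
  expect_true(all(cd0$disruption == 0))
  expect_true(all(cd0$tag_occupancy == 0))
  reg <- c(3, 4, 5, 12, 13, 14)
  conj <- gen_toy_trajectory(toy_trajectory_spec(
    fluct_amplitudes = 0.2, n_frames = 30, seed = 5,
    unfold_schedule = c(rep(1, 5), rep(0.6, 25)), break_region = reg,
    tag = list(near_residues = reg, offset = 4)))
  cd <- contact_disruption(conj, free)
  expect_gt(cor(cd$disruption, cd$tag_occupancy, method = "spearman"), 0.8)
  expect_true(all(cd$disruption >= 0 & cd$disruption <= 1))
  expect_true(all(cd$tag_occupancy >= 0 & cd$tag_occupancy <= 1))
})

test_that("replica averaging returns mean and SEM per frame", {
  reps <- lapply(1:4, function(s) {
    tr <- gen_toy_trajectory(toy_trajectory_spec(n_residues = 20,
                                                 fluct_amplitudes = 0.5,
                                                 n_frames = 10, seed = s))
    contact_fraction(tr, define_native_contacts(tr))
  })
  avg <- replica_average(reps)
  expect_equal(nrow(avg), 10)
  expect_equal(avg$mean[1], mean(vapply(reps, `[`, 0, 1)), tolerance = 1e-12)
  expect_true(all(avg$sem >= 0))
})

test_that("superposition and PCA agree with an independent structural toolkit", {
  skip_if_not_installed("bio3d")
  tr <- gen_toy_trajectory(toy_trajectory_spec(n_residues = 20,
                                               fluct_amplitudes = 0.4,
                                               n_frames = 12, seed = 15))
  ca <- which(tr$topology$atom == "CA")
  xyz <- do.call(rbind, lapply(tr$frames, function(m) as.numeric(t(m[ca, ]))))
  ref_xyz <- as.numeric(t(tr$reference[ca, ]))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = ref_xyz, mobile = xyz))
  rmsd_bio3d <- bio3d::rmsd(ref_xyz, fitted)
  rr <- rmsf_rmsd(tr)
  expect_equal(rr$rmsd, as.numeric(rmsd_bio3d), tolerance = 1e-3)
  pca_bio3d <- bio3d::pca.xyz(fitted)
  p <- suppressWarnings(traj_pca(tr))
  expect_equal(p$variances[1:3], pca_bio3d$sdev[1:3]^2, tolerance = 1e-4)
})
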