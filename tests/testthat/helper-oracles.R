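# Independent brute-force oracles used to cross-check package results.
# These deliberately re-derive each quantity from first principles and
# share no code with the implementation under test.

# exhaustive O(n^2) residue-pair scan for native contacts
oracle_contacts <- function(traj, cutoff = 7, min_sep = 4) {
  topo <- traj$topology
  res <- unique(topo$residue[topo$chain != "T"])
  out <- NULL
  for (a in res) for (b in res) {
    if (b <= a || abs(a - b) < min_sep) next
    ia <- which(topo$residue == a & topo$chain != "T")
    ib <- which(topo$residue == b & topo$chain != "T")
    dmin <- Inf
    for (p in ia) for (q in ib) {
      d <- sqrt(sum((traj$reference[p, ] - traj$reference[q, ])^2))
      dmin <- min(dmin, d)
    }
    if (dmin <= cutoff) out <- rbind(out, c(a, b))
  }
  out
}

# direct mass-weighted radius of gyration
oracle_rg <- function(coords, masses) {
  cen <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, cen)^2)) / sum(masses))
}

# closed-form OLS slope and intercept
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# exhaustive 2-D grid minimization of the two-state melt residual
oracle_melt_grid <- function(axis, signal, temperature_k = 298,
                             dg_range = seq(1, 12, by = 0.05),
                             m_range = seq(0.5, 4, by = 0.02)) {
  rt <- 1.987e-3 * temperature_k
  best <- c(Inf, NA, NA)
  for (dg in dg_range) for (m in m_range) {
    pred <- 1 / (1 + exp((dg - m * axis) / rt))
    rss <- sum((signal - pred)^2)
    if (rss < best[1]) best <- c(rss, dg, m)
  }
  list(dG0 = best[2], m = best[3], rss = best[1])
}

# standard-sized toy used across trajectory tests (20 residues keeps
# the brute-force oracles fast)
toy_static <- function(n_frames = 4, ...) {
  gen_toy_trajectory(toy_trajectory_spec(n_residues = 20,
                                         n_frames = n_frames, ...))
}

rotate_traj <- function(traj, angle = 0.7, shift = c(5, -3, 2)) {
  rot <- matrix(c(cos(angle), -sin(angle), 0,
                  sin(angle), cos(angle), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  traj$frames <- lapply(traj$frames, function(m)
    sweep(m %*% t(rot), 2, shift, "+"))
  traj
}
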