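#!/usr/bin/env Rscript
# Trajectory plasticity metrics on programmed toy trajectories.
#
# A 28-residue beta-grasp-like toy is simulated three ways: (1) native
# fluctuations only; (2) a partial-unfolding schedule that breaks 40%
# of native contacts (alpha and the beta-sheet hydrogen-bond fraction
# fall while RMSD and the radius of gyration rise -- the plasticity
# signature); (3) a tag-conjugate whose broken contacts coincide with
# the tag contact surface, yielding co-localized disruption and
# occupancy maps. A free-energy landscape and PCA summarize the
# sampled conformations.

suppressPackageStartupMessages(library(tagfold))
dir.create("results", showWarnings = FALSE)

# -- native dynamics -------------------------------------------------
native <- gen_toy_trajectory(toy_trajectory_spec(
  fluct_amplitudes = 0.4, n_frames = 120, seed = 601))
contacts <- define_native_contacts(native)

# -- scheduled partial unfolding ------------------------------------
sch <- seq(1, 0.6, length.out = 120)
unfold <- gen_toy_trajectory(toy_trajectory_spec(
  fluct_amplitudes = 0.4, unfold_schedule = sch, n_frames = 120,
  seed = 602))

alpha <- contact_fraction(unfold, contacts)
eta <- hbond_fraction(unfold, list(b1b2 = list(a = 1:8, b = 9:16)))
rr <- rmsf_rmsd(unfold)
gy <- gyration(unfold, loop_mask = 17:28)

profile <- data.frame(frame = seq_along(alpha), alpha = round(alpha, 4),
                      eta_b1b2 = round(as.numeric(eta), 4),
                      rmsd = round(rr$rmsd, 3),
                      rgyr = round(gy$rgyr, 3), rog = round(gy$rog, 3))
write.table(profile, "results/plasticity_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fel <- fel_2d(rr$rmsd, gy$rog, temperature_k = 300, bins = 20)
fel_tab <- expand.grid(rmsd_bin = head(fel$x_breaks, -1),
                       rog_bin = head(fel$y_breaks, -1))
fel_tab$dg <- as.numeric(fel$dg)
write.table(fel_tab[!is.na(fel_tab$dg), ], "results/fel_grid.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

pca <- traj_pca(native)
var_frac <- pca$variances[1:3] / sum(pca$variances)

# -- tag-conjugate disruption map -----------------------------------
free <- gen_toy_trajectory(toy_trajectory_spec(
  fluct_amplitudes = 0.2, n_frames = 60, seed = 603))
reg <- c(3, 4, 5, 12, 13, 14)
conj <- gen_toy_trajectory(toy_trajectory_spec(
  fluct_amplitudes = 0.2, n_frames = 60, seed = 604,
  unfold_schedule = c(rep(1, 10), rep(0.6, 50)), break_region = reg,
  tag = list(near_residues = reg, offset = 4)))
cd <- contact_disruption(conj, free)
write.table(cd, "results/contact_disruption.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Scheduled partial unfolding (first vs last frame):\n")
cat(sprintf("  alpha %.2f -> %.2f | eta %.2f -> %.2f | RMSD %.1f -> %.1f A | Rog %.1f -> %.1f A\n",
            alpha[1], alpha[120], eta[1], eta[120],
            rr$rmsd[1], rr$rmsd[120], gy$rog[1], gy$rog[120]))
cat(sprintf("Free-energy landscape: %d occupied bins, minimum 0 by construction\n",
            sum(!is.na(fel$dg))))
cat(sprintf("PCA of native dynamics: PC1-3 carry %.0f%%, %.0f%%, %.0f%% of the variance\n",
            100 * var_frac[1], 100 * var_frac[2], 100 * var_frac[3]))
cat(sprintf("Disruption vs tag occupancy rank correlation: %.2f\n",
            cor(cd$disruption, cd$tag_occupancy, method = "spearman")))
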