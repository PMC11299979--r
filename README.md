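# tagfold

Quantitative analysis of thermodynamically labile proteasome-targeting
tags and the substrates they destabilize.

Ubiquitin-like modifiers (ULMs) all share the β-grasp fold, but they
differ enormously in stability: ubiquitin unfolds at ~8 kcal/mol while
the inflammation-induced degradation tag Fat10 sits near 2.3 kcal/mol
and melts at 55 °C. That lability matters mechanistically — a soft tag
unfolds readily at the proteasome and, once conjugated, strips free
energy from its substrate, creating the partially unfolded regions the
proteasome needs to engage. `tagfold` is for structural biologists and
biophysicists who want to quantify this behaviour end to end, and to
validate every estimator by parameter recovery on synthetic data with
known ground truth.

The package implements five analysis layers, each paired with a
synthetic-data generator:

| Layer | Model | Outputs |
|---|---|---|
| Equilibrium unfolding | ΔG([D]) = ΔG₀ − m[D]; f_u = 1/(1+e^{ΔG/RT}); 4-parameter logistic for thermal melts | ΔG₀, m, Cm = ΔG₀/m, Tm, ΔΔG |
| Native-state proteolysis | I(t) = A·e^{−k_obs t}; slope(k_obs vs [protease]) = K_op·(k_cat/K_M); ΔG_prot = −RT ln(K_op (k_cat/K_M)/99,000) | k_obs, m_proteolysis, K_op, ΔG_proteolysis |
| Amide temperature coefficients | Tc = Δδ^NH/ΔT by per-residue OLS | Tc, RSS, disorder flags, segment ΔTc_avg |
| Model-free relaxation | Lipari–Szabo J(ω); ¹⁵N dipolar+CSA rates; AIC model selection M1–M4; entropy meter S_conf ∝ (1−S²) | S², τe, Rex, τm, segment −TΔS |
| Trajectory plasticity | native-contact fraction α, β-sheet H-bond fraction η, RMSF/RMSD (Kabsch), Rgyr/Rog, ΔG_i = −k_B T ln(N_i/N₀), PCA, disruption maps | per-frame/per-residue plasticity profiles |

## Worked example: proteolysis energetics of two conjugates

Native-state proteolysis measures how often a folded substrate visits
protease-cleavable, partially open conformations. Here we simulate
thermolysin time courses for two conjugates whose opening free
energies are set to 8.7 and 7.5 kcal/mol, then recover everything
with the pipeline:

```r
library(tagfold)
rt <- 1.987e-3 * 298

ub_cfp    <- run_proteolysis_pipeline(gen_proteolysis(
  proteolysis_spec(kop = exp(-8.7 / rt), noise_sd = 0.03, seed = 301)))
fat10_cfp <- run_proteolysis_pipeline(gen_proteolysis(
  proteolysis_spec(kop = exp(-7.5 / rt), noise_sd = 0.03, seed = 302)))

ub_cfp
#> <proteolysis_result> m_proteolysis = 0.0407 M-1 s-1, K_op = 4.11e-07, dG = 8.707 kcal/mol
fat10_cfp
#> <proteolysis_result> m_proteolysis = 0.304 M-1 s-1, K_op = 3.07e-06, dG = 7.515 kcal/mol

fat10_cfp$m_proteolysis / ub_cfp$m_proteolysis
#> [1] 7.482085
```

The Fat10-tagged construct opens about an order of magnitude more
often (K_op 3.1e-06 vs 4.1e-07): its k_obs rises ~7.5-fold faster with
protease concentration, and ~1.2 kcal/mol less free energy separates
its native state from cleavable conformations. The recovered ΔG values
(8.707, 7.515) match the 8.7/7.5 ground truth to within the fit error,
which is the package's standard of validation for every layer.

The `analysis/` directory holds six numbered drivers that run the
full story — tag unfolding thermodynamics, substrate destabilization
(ΔΔG), proteolysis energetics, temperature-coefficient segment
comparison, model-free entropy mapping, and trajectory plasticity —
each writing its tables under `results/`:

```sh
Rscript analysis/01_unfolding_thermodynamics.R
Rscript analysis/03_proteolysis_energetics.R   # the example above
```

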