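---
title: "Methods: quantifying the thermodynamic lability of proteasome-targeting tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the thermodynamic lability of proteasome-targeting tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Ubiquitin-like modifiers (ULMs) share the beta-grasp fold, but they
are not equally stable. Fat10, a proteasome-targeting tag induced by
inflammatory signalling, is degraded together with its substrate, and
its unusually low thermodynamic stability appears to be part of the
degradation mechanism: a labile tag both unfolds readily itself and
destabilizes the substrate it is conjugated to. `tagfold` implements
the quantitative machinery needed to characterize this behaviour from
five kinds of data — denaturation curves, native-state proteolysis
time courses, amide chemical-shift temperature series, ^15^N
relaxation data, and MD-style coordinate trajectories — together with
synthetic generators for each modality so that every estimator can be
validated by parameter recovery against known ground truth.

## Two-state equilibrium unfolding

Chemical melts are described by the linear extrapolation model. At
denaturant concentration $[D]$ the unfolding free energy is
$\Delta G([D]) = \Delta G_0 - m[D]$, and the apparent fraction
unfolded is $f_u = 1/(1+\exp(\Delta G/RT))$ with
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 298$ K by
default (the melt experiments are performed at 25 °C; the temperature
is an argument). The fit returns $\Delta G_0$ (kcal/mol), the
$m$-value (kcal mol$^{-1}$ M$^{-1}$), and the midpoint
$C_m = \Delta G_0/m$, which holds as an exact algebraic identity in
every returned object.

Curves flagged as normalized are fitted with the pure two-parameter
model. Raw optical signals co-fit linear folded and unfolded
baselines (six parameters); `normalize_curve()` exposes the same
baseline handling as a standalone step, with an endpoint-based
strategy for curves too noisy for a joint fit. Fitting uses
Levenberg–Marquardt (via minpack.lm) from a small multi-start grid:
the midpoint guess comes from the 0.5 crossing of the (roughly)
normalized signal and the $m$ guess from the slope there
($df_u/d[D] = m/4RT$ at the midpoint). Convergence tolerances are
`ftol = 1e-12` on the residual and `1e-10` on parameters, so
noiseless synthetic curves are recovered to well beyond six
significant digits. Degenerate inputs — a constant signal, or no
crossing of the transition — raise errors rather than returning
nonsense; a fitted midpoint outside the sampled range is flagged with
a warning. Thermal melts use an empirical four-parameter logistic in
temperature (the experiment reports a sigmoid and a $T_m$; no van 't
Hoff enthalpy is claimed), and rows are sorted by temperature first so
axis order is irrelevant.

$\Delta\Delta G$ between constructs is the difference of fitted
$\Delta G_0$ with errors summed in quadrature; it refuses to compare
fits performed at different temperatures.

## Native-state proteolysis energetics

A folded protein is cleaved by a nonspecific protease only through
transiently open conformations. Band intensities normalized to a
no-protease control decay as $I(t) = A e^{-k_{obs} t}$; $k_{obs}$
grows linearly with protease concentration, and the slope equals
$K_{op} \cdot (k_{cat}/K_M)$, where $K_{op}$ is the folded-to-open
equilibrium constant. The opening free energy is

$$\Delta G_{proteolysis} = -RT \ln\!\big(K_{op}(k_{cat}/K_M)/99{,}000\big),$$

with 99,000 M$^{-1}$s$^{-1}$ the thermolysin specificity constant
used as the reference; the identities slope $= 99{,}000 \Rightarrow
\Delta G = 0$ and slope $= 99{,}000/e \Rightarrow \Delta G = RT$ are
unit-tested. Amplitudes are bounded in $[0.8, 1.2]$ because
intensities are normalized to the control lane and sparse time courses
otherwise trade amplitude against rate. The $k_{obs}$-vs-concentration
regression is weighted by the inverse variance of the rate fits when
available and keeps a free intercept (background proteolysis); only
the slope enters the free energy. Thermolysin concentrations quoted in
mg/mL are converted with a configurable molecular weight (default
34,600 g/mol). The proteolysis temperature is not stated in the
source experiments; 298 K is the default and an argument everywhere.

## Amide temperature coefficients

The temperature coefficient $T_c = \Delta\delta^{NH}/\Delta T$
(ppb/K) of a backbone amide reports on its hydrogen bond: coefficients
much more negative than the protein mean indicate weak or absent
hydrogen bonds. Per-residue ordinary least squares gives $T_c$, its
standard error and the residual sum of squares
$RSS = \sum_i (y_i - f(x_i))^2$; residues with fewer than three
temperatures are skipped with a warning. Internally everything is in
ppb/K (inputs in ppm are scaled on output). Estimates are invariant to
centering of the temperature axis, which is also unit-tested.

Disorder-prone residues are flagged by the mean-minus-SD rule; the
rule presumes the conventional negative mean of folded amides, so a
positive mean raises a sign-convention error, and a zero-spread input
flags nothing. Because low-sequence-identity proteins cannot be
compared residue by residue, cross-protein comparison runs at the
segment level: coefficients are averaged over named
secondary-structure segments (mean ± SEM; SEM is the package's choice
of error, since the convention "mean + error" does not pin one down),
and $\Delta T_{c,avg} = $ mean(reference) − mean(query) is reported
per segment with quadrature errors. Segments above the mean + error
line are flagged. The bundled default map is a canonical ubiquitin
segmentation (β1 2–7, β2 11–17, α1 23–34, β3 40–45, β4 48–50, α2-loop
51–63, β5 66–71); these boundaries are a documented default, not an
assertion about any particular figure, and callers comparing other
β-grasp proteins should supply their own map.

One flag-rule caveat: a query that is uniformly more flexible than
the reference puts every segment exactly at the mean of the deltas, so
the mean + error rule flags nothing — the rule highlights *localized*
differences by design. The tests therefore assert equality of the
per-segment values for uniform shifts and use a localized forcing case
for the flag itself.

## Model-free analysis of ^15^N relaxation

R$_1$, R$_2$ and heteronuclear NOE of backbone amides are governed by
the ^1^H–^15^N dipolar interaction and the ^15^N CSA through the
spectral density sampled at five frequencies. The Lipari–Szabo form
for isotropic tumbling is

$$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2}
 + \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right],\qquad
 \tau'^{-1} = \tau_m^{-1} + \tau_e^{-1},$$

with exchange broadening $R_{ex}$ added to R$_2$. Physical constants
are fixed in `NMR_CONSTANTS` and documented: $r_{NH} = 1.02$ Å,
$\Delta\sigma(^{15}N) = -160$ ppm, standard gyromagnetic ratios;
isotropic diffusion is assumed throughout (anisotropic tensors are out
of scope). The forward model is validated against an independent
direct evaluation of the textbook expressions, frozen into the test
suite.

Fitting proceeds in three stages. (1) $\tau_m$ is seeded from the
10%-trimmed R$_2$/R$_1$ ratio of rigid residues (NOE > 0.65) by
numerically inverting the rigid-rotor ratio. (2) Each residue is
fitted with the four standard models — M1 ($S^2$), M2 ($S^2, \tau_e$),
M3 ($S^2, R_{ex}$), M4 (all three) — by weighted $\chi^2$
minimization. Optimization runs in natural units ($\tau_e$ in ps,
$R_{ex}$ in s$^{-1}$) because finite-difference gradients on a
seconds-scale $\tau_e$ are numerically useless; three L-BFGS-B starts
are polished by Nelder–Mead. (3) The model per residue is selected by
AIC ($\chi^2 + 2k$). The small-sample corrected AICc is the natural
first choice, but with single-field data each residue has only three
observables, so the correction term $2k(k+1)/(n-k-1)$ degenerates for
$k \ge 2$; plain AIC is the deliberate fallback. $\tau_m$ is then
refined by minimizing the summed $\chi^2$ of the exchange-free
residues (selected models M1/M2, model choice held fixed) over a ±10%
bracket that is re-centered until the optimum is interior, and model
selection is re-run at the refined value. Residues that fail to
converge are flagged and excluded from segment averages.

Order parameters are converted to conformational entropy with a
linear entropy meter, $S_{conf} = s_{slope}(1 - S^2) + s_0$, default
slope 5 cal mol$^{-1}$ K$^{-1}$ per unit $(1-S^2)$ — of the order of
published NMR entropy-meter calibrations, and exposed as an argument.
The exact calibration constants used in any given study live in its
cited references, so absolute $-T\Delta S$ values are not
reproducible here; every comparison in this package is a
*difference*, so the additive constant cancels and only the pattern
across segments is interpreted. $-T\Delta S$ per segment uses the same
segment machinery, sign convention $\Delta S_{conf} =
S_{conf}^{ref} - S_{conf}^{query}$ (positive $-T\Delta S$ = query more
flexible), quadrature errors and the mean + error flag line.

## Trajectory plasticity metrics

Native contacts are residue pairs whose minimum heavy-atom distance
in the reference structure is ≤ 7 Å, excluding pairs closer than 4 in
sequence (the "long-range" convention; the source method names a
7 Å cutoff but not the atom rule, so minimum heavy-atom distance is
the package's documented choice, with Cα-only toys supported). The
per-frame fraction of retained native contacts is α; the per-frame
fraction of native β-sheet backbone N···O pairs within 3.5 Å per
strand pair is η (no angle term — the criterion is the stated distance
cutoff on backbone atoms). RMSD and per-residue RMSF are computed
after Kabsch least-squares superposition on Cα atoms (mass-weighting
off); radii of gyration are mass-weighted, reported both for the full
protein (Rog) and a loop-excluded selection (Rgyr, caller-supplied
mask). Free-energy landscapes Boltzmann-invert a 2D histogram of two
structural coordinates, $\Delta G_i = -k_B T \ln(N_i/N_0)$ with
$N_0$ the most populated bin, 50×50 bins over the observed range by
default; empty bins are masked (NA), never zero, and the minimum is
exactly 0 by construction. PCA eigen-decomposes the covariance of
superposed Cα coordinates; variances are non-increasing, projections
are per frame, and structures interpolating the extreme PC1
projections can be exported. Replica series are combined as
mean ± SEM across replicas.

Contact-disruption analysis compares a free-substrate and a
tag-conjugate trajectory sharing substrate numbering: per substrate
residue it reports the mean retained long-range native-contact count
in each run, their difference rescaled to [0, 1] (disruption map), and
the fraction of conjugate frames with any tag atom within the contact
cutoff (tag-occupancy map). Overlap of the two maps is summarized by
rank correlation.

## What the synthetic generators emulate — and what they do not

Each generator is the exact forward model of its fitter plus additive
Gaussian noise on normalized signals (or relative Gaussian noise on
rates) — the standard instrument-noise assumption; the source
experiments do not state noise magnitudes, so the defaults used in
the tests (0.02 on normalized melt signals, 0.03 on band intensities,
0.002–0.003 ppm on shifts, 2% on relaxation rates) are the package's
own choices of plausible instrument noise, stated here once and not
tuned per experiment. Reported relaxation errors equal the applied
noise level, with a 10$^{-6}$ relative floor at zero noise so
$\chi^2$ weights stay finite while still reflecting that the data are
exact. Every generator records its ground truth in the returned
object and draws one RNG stream per residue/lane (seed + index), so
extending a dataset does not reshuffle earlier draws, and fixed seeds
give bit-identical outputs.

The toy trajectory is an idealized backbone (N, CA, O per residue):
two 8-residue antiparallel strands 4.8 Å apart whose cross-strand
N···O distances are 2.8 Å (a native hydrogen-bond ladder), plus a
helix placed away from the sheet. Unfolding schedules are realized by
detaching whole residues from the native environment until the
retained contact fraction reaches the scheduled value; because a
residue participates in several contacts, the schedule is met at
residue granularity and the realized per-frame fraction is stored as
ground truth. An optional pseudo-tag chain places one atom near each
chosen substrate residue and tracks it through the trajectory, which
is how the disruption/occupancy co-localization case is constructed.

Passing these tests demonstrates that the estimators are unbiased
and correctly implemented against their own forward models. It does
not demonstrate robustness to what real data add: sloping and curved
baselines beyond linear, aggregation during melts, deviations from
two-state behaviour, EX1-regime proteolysis, anisotropic tumbling,
multi-state exchange, curved shift-vs-temperature dependence, or
force-field realism in trajectories. Those are the standard caveats
of each method and are deliberately out of scope.

## Problem sizes and runtime

The test and analysis problem sizes are chosen so the whole suite
runs in about a minute on a single core: melts of 31–76 points,
proteolysis series of 4 concentrations × 8 time points, 71-residue
shift tables, 8–12-residue relaxation sets for the model-free
round-trips (71 residues in the analysis driver), and 20–28-residue
toys with ≤ 120 frames. Recovery statistics average 10 seeds; the
equilibrium-unfolding recovery property uses 60 curves. All of these
are arguments, not limits.
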