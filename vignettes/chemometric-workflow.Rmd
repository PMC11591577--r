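---
title: "Chemometric discrimination of blood ATR-FTIR fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric discrimination of blood ATR-FTIR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirchemo)
```

## The problem

Attenuated-total-reflection FTIR spectroscopy of a drop of blood-derived
fluid produces an absorbance curve over the mid-infrared *fingerprint
region* (1500-1000 cm⁻¹), a superposition of protein, lipid,
carbohydrate and nucleic-acid bands. Diseases that alter the circulating
metabolome shift a handful of these bands by small amounts. The
chemometric task is to decide, from a few dozen spectra, (i) whether
patient groups can be discriminated, (ii) which wavenumbers carry the
discrimination, and (iii) how well a *single* band performs as a
diagnostic score. `ftirchemo` implements this workflow end to end for
cohorts of ALS patients at diagnosis (`ALS_T0`), after six months
(`ALS_T6`), healthy controls (`HC`) and other neuromuscular disorders
(`ON`), and ships a synthetic cohort generator so every stage can be
validated against planted ground truth.

## The synthetic cohort

No patient data are distributed; `generate_cohort()` emulates the study
design instead. Each spectrum is a sum of ~10 Gaussian bands
(`default_bands()`) with three layers of variation:

* **Biological variability**: every base-band amplitude is jittered per
  sample with relative sd `band_cv` (default 0.05), and the planted
  group effects are themselves heterogeneous across patients
  (`effect_cv` = 0.4). Without within-class biological structure the
  group signal would be a rank-one artifact that no variable-selection
  benchmark can meaningfully probe.
* **Group effects**: absorbance shifts planted at three marker
  wavenumbers — 1335.5, 1304 and 1449.5 cm⁻¹ — with group-specific
  signs and magnitudes (`default_group_effects()`). Under the default
  preprocessing these correspond to ~2.5 standardized within-class
  units, a strong but not degenerate separation.
* **Instrument artifacts**: per replicate, a multiplicative scatter
  factor (0.97-1.03), a linear baseline `a + b·nu`, and i.i.d. Gaussian
  noise (sd 0.004 AU). Each sample is "measured" three times and the
  replicates averaged, so effective noise drops by √3.

Group sizes default to 19/16/15/7 (ALS_T0/ALS_T6/HC/ON). The grid runs
1500 → 1000 cm⁻¹ at 0.5 cm⁻¹ (1001 points), so marker positions quoted
at half-wavenumber precision are addressable exactly even though the
optical resolution of such instruments (4 cm⁻¹) is coarser.

What the generator does **not** emulate: water-vapour and CO₂ lines,
ATR penetration-depth dispersion, Mie-type scattering curvature,
instrument drift between sessions, label noise, and correlated
metabolic co-variation beyond the per-band jitter. Green tests therefore
demonstrate algorithmic correctness and sane statistical behaviour on a
plausible spectral model — not clinical performance.

## Preprocessing

`preprocess()` applies, in a fixed order: crop to the closed interval
[1000, 1500] cm⁻¹ → per-spectrum normalization (unit Euclidean norm by
default; SNV available) → 5-point moving average → 11-point
Savitzky-Golay second derivative (polynomial order 3). The derivative is
reported per cm² (divided by the squared grid step) so its values are
grid-invariant; band maxima appear as negative troughs. Autoscaling
(centre/scale each wavenumber using **training** statistics, n−1
denominator) happens inside the model-fitting stages, never on the full
data, so no test-sample statistic can leak into a fitted model.
Zero-variance columns scale by 1 with a warning — after centering they
carry no information.

Choices left open by common practice and fixed here: polynomial order 3
and moving-average window 5 (both exposed in `preprocess_config()`);
vector normalization before smoothing/derivative (SNV gives the same
scatter-removal property); edge points of the Savitzky-Golay filter come
from the one-sided polynomial fits. Interior points are exact for
polynomials up to the filter order — a property the test-suite checks to
1e-9 on random cubics.

## SELECT + LDA

`select_decorrelate()` scores each wavenumber by the Fisher ratio
(between-class over pooled within-class variance), picks the argmax
(ties to the lower column index), then projects every remaining column
onto the orthogonal complement of the pick, and repeats. The Fisher
ratio stands in for the selection weight of the classical stepwise
decorrelation procedure; for two balanced classes its ranking coincides
with the squared point-biserial correlation ranking. The retained count
obeys the 3:1 sample-to-variable rule, `floor(n/3)`
(`max_variables_rule()`); `run_pipeline()` clamps a too-ambitious
request with a message.

A consequence worth stating plainly: *decorrelation discards redundant
markers by design*. When several planted bands shift together with the
class, the first pick absorbs their shared signal and the others are
orthogonalized away; a SELECT list is not an exhaustive list of
informative bands. This is why the package compares strategies at band
level (`consensus_bands()`, `top_bands()`) rather than expecting every
marker in every list.

`lda_fit()` classifies by Mahalanobis distance to class means under the
pooled within-class covariance with **equal priors** (symmetric
per-class reporting for unbalanced groups); exact ties go to the first
class label. If the pooled covariance is numerically singular a ridge of
`1e-8·trace/p` is added. Canonical variates (eigenvectors of W⁻¹B) are
exported for score plots. The LDA operates on the original autoscaled
values of the selected wavenumbers, not on the decorrelated residuals,
so the model applies directly to new spectra.

Two cross-validation modes are provided and must not be confused:

* `loo_crossval()` refits only the LDA inside each fold, on the fixed
  selected subset — the published-workflow convention. On null data with
  ~1000 candidate variables this estimate is **grossly optimistic**
  (near 100%), because the left-out sample participated in selection.
* `nested_loo_select_lda()` re-runs autoscaling **and** SELECT inside
  every fold; on null cohorts it stays at chance (measured mean 0.45).
  This is the honest generalization estimate, and it is the one the
  null-calibration tests rely on. Note that even it is overdispersed
  relative to an i.i.d. binomial reference, since LOO predictions share
  almost all their training data.

Classification tables report per-class % correct and the total rate
(sample-weighted mean of the per-class rates, i.e. overall accuracy) for
resubstitution, internal CV and the external test set, mirroring the
field's standard three-column layout.

## SIMCA

Each class gets its own centered PCA model (`simca_fit()`); the
component count is chosen per class by leave-one-out PRESS, capped at 3
(small classes cannot support deeper models; override available). The
residual dispersion conventions are `sd_j = √(Σe²/(n−A−1))` per variable
and `s0 = √(ΣΣe²/((p−A)(n−A−1)))` pooled. An object's distance is
`s_i = √(Σe²/(p−A))` and membership is tested with
`F_i = s_i²/s0²` against `F(p−A, (n−A−1)(p−A))` — the classic SIMCA
degrees-of-freedom dialect; others exist. *Open* classification may
accept an object into several classes or none; *forced* classification
assigns to `argmin F_i/F_crit`. "Efficiency" is reported as the
geometric mean of a class model's sensitivity and specificity (open
variant and forced variant) — a common usage of the term where no
formal definition is standard.

Modelling power `MP_j = 1 − sd_resid/sd_raw` (clipped to [0, 1])
measures how well the components describe a variable inside its class;
discriminant power
`DP_j = √((S²(A→B)+S²(B→A))/(S²(A→A)+S²(B→B)))` uses mean squared
projection residuals (means, not sums, so unbalanced classes do not
bias the ratio); DP ≈ 1 means non-discriminant. The power table is
sorted by descending DP with one MP column per class.

## PLS-DA, OPLS-DA and validation

`plsda_fit()` is a NIPALS implementation on centered one-per-class
dummy responses (also in the 2-class case, for symmetric reporting).
`oplsda_fit()` collapses two classes to a centered ±-type response,
splits off `n_orth` class-orthogonal components (weights from the part
of the X-loading orthogonal to the predictive weight), and fits a single
predictive component on the filtered matrix; with no structured
orthogonal variation it reduces to 1-component PLS.

Validation quantities: `R2Y` (fit), `Q2Y` from stratified 5-fold
cross-validation with a *full refit per fold including the autoscaler*
(`q2_crossval()`), a label-permutation test
(`p = (1+#{perm ≥ obs})/(1+n_perm)`, with Q2Y as the primary statistic
and R2Y alongside), and an approximate cross-validated-residual ANOVA
`F = ((SS_tot−PRESS)/d1)/(PRESS/d2)` with `d1` = component count and
`d2 = n − d1 − 1` — a pragmatic convention, labelled approximate, since
no canonical dof choice exists for CV residuals. VIP scores follow
`VIP_j = √(p·Σ_a SSY_a w_ja²/Σ_a SSY_a)` and satisfy mean(VIP²) = 1
identically.

Because a VIP profile on a 0.5 cm⁻¹ grid is smooth, its raw top-10 grid
points usually sit inside one or two bands. `top_bands()` therefore
picks greedy local maxima with a minimum separation (4 cm⁻¹ default),
which is how a spectroscopist reads a VIP plot; the pipeline's "top-10
VIP" is band-level.

## ROC diagnostics

`roc_curve()` evaluates one wavenumber as a diagnostic score: cut points
at midpoints between adjacent sorted values (plus ±∞), AUC from the
rank-based Mann-Whitney statistic with ties counted ½, and a two-sided
p-value (exact enumeration when `n₁·n₂ ≤ 400` and untied, tie-corrected
normal approximation otherwise). The decision direction
(`positive-if-low` / `positive-if-high`) is auto-chosen to make
AUC ≥ 0.5 and always reported explicitly — second-derivative intensities
can go either way depending on whether a band strengthens or weakens in
the disease group. The operating point maximizes the Youden index
`J = sens + spec − 1`; ties break toward higher sensitivity, then the
lower cut.

## The pipeline

`run_pipeline()` executes two comparisons that mirror the study design:
`ALS_T0` vs `HC` (5 + 5 external test samples, OPLS-DA route) and
`ALS_T0` vs `ALS_T6` vs `ON` (2 per class external, PLS-DA route). Per
comparison: stratified split → preprocessing → train-fitted autoscaling
→ PCA overview with **advisory** 99% Hotelling-T²/Q flags (no automatic
removal — there is no defensible automatic rule at these sample sizes)
→ SELECT-LDA with the three-column report → SIMCA on the selected
variables → OPLS-DA/PLS-DA validation → band-level VIP top-10 →
consensus bands (SELECT ∩ VIP within 1 cm⁻¹) → a ROC per consensus
band. All randomness derives from one root seed through named
substreams, so a config + seed pair reproduces every table byte for
byte; the JSON manifest records the config hash and seed.

## Numerical and design notes

* Perfect-separation Fisher weights map to a finite sentinel (1e12) so
  argmax stays ordered; SELECT stops early (with a warning) if the best
  remaining column is numerically zero.
* `simca_fit()` accepts `A = rank` (data exactly on an A-dimensional
  subspace gives `s0 = 0`); residuals at numerical-noise level count as
  in-plane (`F = 0`).
* Marker *recovery* in the tests means a reported band within the
  planted bump's 2σ support (8 cm⁻¹): band overlap and effect
  heterogeneity legitimately shift the most discriminative grid point a
  few points off the planted center, and grid-point equality would test
  RNG minutiae rather than band identification.
* Test problem sizes: property tests use 20-200 random instances; the
  cohort-level checks use 50 seeded cohorts at the default design
  (19/15 two-class), with 39-199 permutations per permutation test.

## Known limitations

* The fixed-subset LOO convention is optimistically biased (documented
  above); use the nested variant for honest error estimates.
* DP is defined pairwise; the three-class power table reports MP only.
* CV-ANOVA degrees of freedom are approximate by construction.
* The generator's band model is Gaussian; Lorentzian/Voigt shapes and
  atmospheric interferences are out of scope, as are EMSC and
  rubber-band baseline correction.
* At n ≈ 30-60 every rate in the report tables has a wide sampling
  distribution; single-run percentages should be read with binomial
  error bars in mind.
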