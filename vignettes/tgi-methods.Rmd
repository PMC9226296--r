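---
title: "Temporal grading of dynamic brain-network topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal grading of dynamic brain-network topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgindex)
```

## The problem

Chronic back pain reorganizes large-scale brain networks, and the
reorganization is not static: the topology of resting-state functional
connectivity fluctuates on the scale of minutes. This package implements a
pipeline that (i) estimates those fluctuations with sliding-window
correlation networks from parcellated BOLD time series, (ii) summarizes
each window with nodal graph metrics, (iii) condenses a patient's whole
metric time course into one number per region — the *temporal grading
index* (TGI) — measuring how the patient's deviation from the
healthy-control norm scales with that norm, and (iv) predicts self-reported
pain intensity (VAS, 0–10) from TGI features with penalized regression
under repeated cross-validation.

## The model, stage by stage

### Preprocessing and quality control

Input is one table per subject: T time points by n regions, at a repetition
time of 2.5 s. Runs arrive at 245 or 305 volumes; long runs lose their
trailing 60 volumes, and every run then loses its first 5 for signal
equilibration, leaving T = 240. Band-pass filtering retains 0.01–0.1 Hz,
realized as a zero-phase (forward–backward) Butterworth design of order 2;
only the band is scientifically meaningful, the filter family and order are
conventional defaults and are exposed in `default_config()`.

Subjects are excluded when any translation exceeds 2 mm, any rotation
exceeds 2°, or mean framewise displacement (FD) exceeds 0.2 mm. FD follows
the Power convention: the sum of absolute frame-to-frame translation
increments plus rotation increments converted to arc length on a 50 mm
sphere. The Jenkinson variant would differ in the third decimal for typical
traces; the Power form is the default because it is the convention of the
motion-QC literature this rule comes from.

### Sliding-window networks

Windows are rectangular, 50 TRs long, advancing 1 TR, giving
`floor((240 − 50)/1) + 1 = 191` windows. Windows shorter than one period of
the lowest retained frequency (1/0.01 Hz = 100 s) trigger a warning, since
windowed correlations become spurious in that regime; at 50 × 2.5 s = 125 s
the default is safe. Within each window, pairwise Pearson correlation is
computed; negative values are set to zero (not folded to absolute values:
the downstream metrics assume nonnegative weights, and a negative
correlation is treated as "no evidence of coupling", the same policy used
for regions that are constant within a window), and the diagonal is zeroed.
Correlations are not Fisher-z transformed by default — a flag exists, but
the transform changes the weight scale that the clustering normalization
assumes.

### Nodal metrics

Three metrics per window and region, all on the weighted, unthresholded
matrix:

* **degree** — nonzero-neighbor count or summed strength. On a single
  subject's matrices a zero arises exactly where a correlation was
  negative, so the count fluctuates meaningfully across windows and
  `nodal_degree()` defaults to it. The TGI pipeline, however, defaults to
  *strength*: the deviation regression needs a norm course with variance,
  and count degree evaluated on the *averaged* control network is constant
  (averaging the zeroed-negative matrices leaves essentially no exact
  zeros), which would render every degree TGI undefined.
* **clustering coefficient** — Onnela's weighted form: weights are scaled
  by the slice maximum, and node *i* gets the sum of cube-rooted triangle
  weight products normalized by k(k−1) over its nonzero-neighbor count k.
  Nodes with fewer than two neighbors get 0.
* **participation coefficient** — the strength-based Guimerà–Amaral form,
  `1 − Σ_m (s_im/s_i)²`, over a 9-module partition: seven cortical
  functional systems plus a subcortical module (amygdala, basal ganglia,
  thalamus; atlas labels 211–214, 219–230, 231–246) and a cerebellar module
  (labels 247–274). Isolated nodes get 0, the toolbox convention. The
  cortex-to-system lookup is supplied by the user for real atlases;
  `default_partition()` ships a synthetic contiguous-block assignment for
  the 214 cortical labels, which is sufficient for simulation studies but
  is *not* the anatomical Yeo assignment.

Both clustering (through its max-normalization) and participation are
invariant to rescaling all weights by a positive constant, and all three
metrics commute with node permutation; the tests enforce these properties
and brute-force equivalence on every graph with up to five nodes.

### The temporal grading index

For region *j*, let `x_t` be the norm property time course — the metric
evaluated on the window-wise *average* control network (metric after
averaging; averaging metrics across control subjects instead is available
as a sensitivity option) — and `y_t` the patient's course. The TGI is the
OLS slope `k` of

    y − x = k·x + b

fitted across the 191 windows. `k = 0` means the patient tracks the norm;
`k > 0` means the deviation grows where the norm is high; `k < 0` means it
shrinks. The intercept `b` is retained in diagnostics but excluded from
features, since the index of interest is the scaling of the deviation, not
its offset. Regions whose norm course is flat (variance below 1e−12) have
no defined slope; they are imputed as 0 — the conservative "no deviation"
value — and flagged, keeping the feature dimension fixed across subjects.

Per-property slope vectors are concatenated across regions, blocks stacked
side by side (`degree:R1 … pc:Rn`), and each column is z-scored. During
cross-validation the z-scoring statistics are estimated on training
subjects only; the z-scored combination is what "combined features" means
throughout.

### Prediction

Three families, each minimizing its stated objective with an unpenalized
intercept:

* linear ε-SVR with budget C (hyperparameters (C, ε));
* lasso: `(1/2n)‖y − Xβ‖² + λ‖β‖₁`;
* elastic net: `(1/2n)‖y − Xβ‖² + λ‖β‖₁ + α‖β‖₂²` (the L2 term is the
  squared norm, so α = 0 reduces exactly to the lasso).

The squared error is per-sample, the convention of the standard lasso
solvers (scikit-learn, MATLAB's `lasso`, glmnet up to a factor): under it a
fixed λ grid spans the same weak-to-mean-collapsing penalty range at any
sample size, which is what makes a printed grid like {0.10, 0.15, …, 1}
meaningful. On the summed-RSS scale that same grid would be nearly
penalty-free for any realistic n. The lasso λ is grid-searched over
{0.10, 0.15, …, 1}. SVR and elastic net
use a two-step search: a coarse logarithmic grid (9 points per axis; C in
2⁻⁵…2⁵, ε in 0.01…1, elastic-net λ in 0.01…1, α in 0…1 linear), then nine
linear points between the coarse optimum's neighbors. Selection is by
5-fold inner-CV mean MSE with deterministic tie-breaking toward the
smallest hyperparameters. Internally, lasso and elastic-net fits are
computed with glmnet — with the penalty mapped onto glmnet's
parameterization, the ridge term corrected for glmnet's internal response
scaling, and a final exact coordinate-descent polish that drives the KKT
residual of the stated objective below 1e−10; the test suite checks those
KKT conditions against an independent subgradient oracle.

Outer evaluation is 5-fold cross-validation repeated ten times; the
reported summary is the mean ± sd of the ten repeat-level mean MSEs (not of
the fifty folds — the repeat level is the exchangeable unit).

### Bias adjustment

Penalized predictors compress the target range, so the signed error
Δ = prediction − target correlates negatively with the target. The
adjustment fits Δ = μ·target + φ on the training fold and subtracts the
offset μΩ + φ from each test prediction, with Ω the test subject's *actual*
target. Using Ω at test time follows the published scheme and is an
acknowledged circularity: under a pure null it deflates the MSE toward the
variance of the prediction noise rather than the target variance. For that
reason the adjustment is a flag (`bias_adjust = FALSE` removes all
test-target usage), and the package's own null-calibration checks run with
the adjustment off. The algebra is exact: for any affine bias
`pred = a·target + c`, the corrected predictions equal the target
identically.

### Group statistics

The "two-sample t-test with covariates" is the group coefficient of an OLS
on group plus age, gender, and BDI (algebraically ANCOVA); with no
covariates it reduces exactly to the pooled t-test. Gender uses a 2×2
chi-square (no continuity correction by default). TGI–BDI association uses
Pearson correlation. Multiple comparisons are corrected by
Benjamini–Hochberg within each property's family of regions, q < 0.05.

## The synthetic cohort: what it does and does not emulate

Engineering BOLD signals to hit exact graph-metric targets is ill-posed, so
ground truth is injected at two tiers.

**Tier A — time series.** Each subject is zero-mean multivariate Gaussian
noise whose correlation matrix switches among a small number of
module-structured positive-definite states (within-module baseline 0.35,
between 0.05, random low-rank perturbation, eigenvalue-clamped), with
geometric dwell times (default mean 30 TRs, 4 states). Patients draw from
states whose within-module correlations are boosted and between-module
correlations damped by `cbp_shift`; at 0 the groups are exchangeable, which
the tests exploit for null calibration. Defaults mirror the emulated cohort design:
29 controls, 30 patients, 274 regions, 245 volumes at TR 2.5 s; VAS
6.8 ± 1.7 for patients, BDI 6.3 ± 5.6 vs 1.3 ± 2.2, age ≈ 50 ± 9, and a
17/13-ish gender split — the demographic profile of a typical chronic
back pain cohort of this size. The shift magnitude has no empirical
anchor in windowed-property effect sizes, so it is a calibration choice; 0.5 gives comfortably
detectable group differences at n = 30/group. Tier A exercises the full
pipeline end to end but cannot certify metric values.

**Tier B — property matrices.** The deviation model is inverted: given a
norm course `x`, a patient's course is `y = (1+k)·x + b + ε` with known
per-region `k`, `b` and i.i.d. Gaussian ε. This gives exact ground truth
for the TGI estimator: noiseless recovery is exact to numerical precision,
and noisy recovery matches the closed-form OLS standard error
`σ/√(var(x)·(t−1))`, which the tests check both as an RMSE ratio and as
95%-CI coverage.

**VAS coupling.** Targets are `clip(intercept + Z·w + ε, 0, 10)` on the
standardized features. The default coupling in the analysis scripts uses
three active features with weights (1.2, −1.0, 0.8) — signal sd ≈ 1.75,
matching the emulated cohort's VAS sd of 1.7 — intercept 5, and noise sd 0.5.
Generators warn when more than 5% of draws clip, since heavy clipping
breaks the linearity the generator promises.

What tier A does *not* model: hemodynamics, physiological noise, scanner
drift, spatial smoothness, or any anatomically realistic module layout.
Passing tests therefore certify the pipeline's statistical machinery — not
that real BOLD data satisfy the deviation-slope model.

## Numerical choices and degenerate inputs

* Windowed correlation of a within-window-constant region is 0 with a
  warning (finite stacks, "no evidence of coupling"), never NaN.
* Flat-norm TGI regions: imputed 0, flagged, never silently dropped.
* Zero-variance feature columns standardize to 0 with a warning.
* Constant training targets: penalized fits return the target mean; the
  bias model refuses (its slope is undefined).
* Grid-search ties break to the smallest hyperparameters, making repeated
  runs bit-identical.
* All randomness derives from one master seed through a fixed integer hash
  per stage and index (`derive_seed`), so any stage can be re-run alone.

## Problem sizes used in the checks

The packaged checks run the estimator-level verifications at full pipeline
scale (t = 191 windows, 30 patients, 100 regions for TGI recovery; n = 60
subjects with 300 features for prediction) and the pipeline-level
simulations at reduced scale (tens of regions, shortened series), chosen so
the whole suite completes in minutes on one core while keeping every
statistical conclusion at the stated power. The analysis scripts under
`analysis/` run a 60-region cohort for the same reason; every stage is
size-agnostic and runs identically at 274 regions.

## Known limitations

* The default cortical-module assignment is synthetic; participation
  coefficients on real data need the atlas's own network lookup.
* The bias adjustment reproduces the published scheme including its use of
  the test subject's true score; MSEs with the adjustment on are not
  comparable to leakage-free MSEs, and both are reported.
* Whether degree/clustering should be computed on binarized matrices is
  not settled by the source description; the default (count degree,
  weighted clustering) is an assumption, with modes for the alternatives.
* Published MSE figures for this kind of analysis come from real cohorts
  that are not redistributable; the synthetic cohort verifies estimator
  correctness and calibration, not any particular empirical number.
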