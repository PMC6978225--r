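---
title: "White matter brain age: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White matter brain age: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tractage)
```

This vignette is the package's account of the science it implements: the
generative model behind the synthetic cohorts, each analysis stage with its
assumptions and tunable parameters, the numerical choices that are easy to
miss in code, and what the test suite does and does not establish about real
data.

## The analysis in one paragraph

A subject's white matter is summarized as a *connectogram*: seven diffusion
indices (GFA, AD, RD, MD, NG, NGO, NGP — anisotropy and non-Gaussianity
unitless, diffusivities in um^2/ms) sampled at 100 normalized steps along 76
predefined tract bundles.  Each connectogram is reduced to 532 tract features
(76 tracts x 7 indices) by along-tract smoothing, per-step normalization and
an age-association-weighted average over steps.  A sparse autoencoder
compresses the 532 features to 179; a Gaussian-process regression predicts
age from the compact features plus sex.  The *predicted age difference*
(PAD = predicted minus chronological age) is the individual-level readout.
Deviation from normative aging is quantified per tract feature as a z-score
against an age- and sex-conditioned normative model, and PAD is attributed to
tracts through effect-size-ranked feature selection, PCA, and regression of
PAD on the first component.  Clinical relevance is assessed with
confound-adjusted correlations and bootstrap intervals.

## The synthetic cohort generator

No imaging data ship with this package; every analysis runs on cohorts drawn
from `generate_cohort()` / `make_study_suite()`.  The generator is a
stand-in for MRI-derived inputs, and all of its structural choices are the
package's own.

The value of cell (tract *t*, index *k*) at step *s* for subject *i* is

```
y = B_tk(s) + beta_tk (b_i - 45) + gamma_tk (b_i - 45)^2
    + delta_tk male_i + u_itk + eps_itks
```

* `B_tk(s)` — a smooth baseline: index-specific level plus a 3-term cosine
  series with cell-specific amplitudes.  Smoothness gives the smoothing
  stage something non-trivial to act on.  All per-cell constants come from a
  deterministic sine-hash of the cell position, not from the RNG, so the
  simulated "population" is a fixed property of the package.
* `beta, gamma` — linear and quadratic age effects.  Signs follow adult
  aging qualitatively (GFA and non-Gaussianity decline, diffusivities rise);
  magnitudes differ across cells and about 30% of cells are flat, so the
  age-association weighting has genuine contrast.
* `b_i = a_i + d_i` — the subject's latent *biological* brain age:
  chronological age plus a subject-level deviation `d_i ~ N(0, brainage_sd)`
  with `brainage_sd = 5` years by default.  This is the load-bearing design
  choice.  Without a shared latent factor, hundreds of nearly independent
  informative cells would pin chronological age to within a year or two,
  which no diffusion-MRI brain-age study achieves; prediction errors in the
  literature sit near MAE 4-6 years.  With it, the model's error floor is
  the biological deviation itself, PAD acquires its intended meaning (an
  estimate of `d_i`), and 10-fold cross-validation of the default pipeline
  lands at r ~ 0.96, RMSE ~ 5.7 y, MAE ~ 4.6 y — the regime reported for
  real cohorts of this size.
* `u_itk ~ N(0, subject_sd = 0.03)` — per-subject, per-cell random
  intercepts; `eps ~ N(0, step_sd = 0.06)` — step-level noise (index
  units).
* Sex enters as an additive per-cell offset (males coded 1).

`make_study_suite()` reproduces the study structure: training n = 300 (ages
18-92, sampled more densely below 40 and above 60 than in between), testing
n = 40, normative n = 524 (ages 7-92), and three study groups matched in age
and sex *by construction* — controls n = 37 (17 M), left-patient group
n = 18 (10 M), right-patient group n = 17 (9 M).  Matching uses
proportional interleaving of the sorted age pool, so group means agree to a
fraction of a year.  Patient clinical covariates are drawn with the
published cohort moments (e.g. right group: onset 12.5 +/- 6.7 y, duration
25.5 +/- 9.3 y, seizure frequency 1.09 +/- 1.31 per month, 2.71 +/- 0.69
drug classes).  Onset + duration is *not* constrained to equal age.

### Lesions

`lesion_spec()` injects disease effects with known ground truth.  Each
targeted tract's profile is shifted per index by
`delta_k x severity x healthy_SD`, where the deltas default to RD +1,
MD +0.8, GFA -0.6 (in z-units of the healthy cell SD) and severity is a
deterministic, floor-at-zero linear function of onset, duration and seizure
frequency centered at typical patient values.

A purely focal lesion (the default, `diffuse_scale = 0`) keeps every
non-target tract bit-identical — the contract the locality tests rely on.
The study-suite lesions additionally spread a 25% echo of the focal shift
across all other tracts (`diffuse_scale = 0.25`).  This is deliberate and
matters: a shift confined to 15 of 532 cells is nearly orthogonal to the
healthy co-variation manifold the autoencoder learns, and its encoding —
hence its effect on predicted age — is essentially arbitrary (in pilot runs
it *lowered* predicted age).  Real temporal-lobe epilepsy shows widespread
white matter involvement well beyond the focal network, and once the lesion
carries a diffuse aging-like component the predicted-age response is
positive, monotone in severity, and saturating — the default suite's
right-lateralized group shows the strongly elevated mean PAD the demo
report prints.  The focal component still dominates per-cell effect sizes
(4:1), which is what the selection and attribution recovery tests exploit.

## Feature pipeline

Order: smoothing, then normalization, then weighting — each stage fitted on
the training cohort only and frozen for every other cohort (no statistics
ever leak from test or patient data).

* **Smoothing** (`smooth_sigma = 2` steps, truncation 3 sigma, reflect
  boundary): a normalized discrete Gaussian applied independently per
  tract x index profile.  Rows of the convolution matrix sum to 1 after
  boundary folding, so constants pass through exactly and `sigma = 0` is the
  identity.  The kernel width is configurable; 2 steps suppresses step-level
  noise without erasing profile shape at the 100-step resolution.
* **Normalization**: per (tract, step, index) cell, subtract the training
  mean and divide by the training SD (n-1).  Cells with zero training SD are
  flagged; normalizing through them is an error unless an explicit epsilon
  substitute is supplied — silent division by "almost zero" is the failure
  mode this guards against.
* **Weighting**: per cell, OLS of the normalized value on (1, age, age^2);
  the weight of a step is `-log10(p)` of the model-vs-intercept F test with
  (2, n-3) degrees of freedom.  The F test is the overall model test — the
  plainest reading of "the p-value of the F statistic" for a two-regressor
  model.  p-values are floored at `1e-300` so weights stay finite, and the
  100 weights of each profile are renormalized to sum to 1 (flag
  `normalize_weights`), making the reduction a true weighted mean.  Sex is
  deliberately excluded from the weighting model (it enters the age model
  instead).  The weighted average of the 100 steps yields the 532-vector.

## Autoencoder

One hidden layer of 179 sigmoid units, linear output, on column-standardized
features (standardization frozen from training).  Loss = MSE + KL sparsity
penalty toward a mean activation of 0.05 (weight 1.0) + L2 penalty (1e-4).
Training is full-batch L-BFGS for up to 1600 iterations, seeded and
bit-reproducible; the optimizer identity is not part of the contract — the
loss definition and seeded determinism are.  *Reconstruction rate* is
defined here as variance explained by the reconstruction on the
standardized scale (R^2 x 100); under the default generator it reaches
~89% on n = 300 training subjects (the pilot-derived bound asserted in the
tests is 85%).  With a linear activation and the penalties off, the model
recovers the PCA optimum on low-rank data to within optimizer noise — the
oracle test for the implementation.

The encoder generalizes imperfectly: for subjects not seen in training, the
compact representation adds appreciable noise beyond the GP's own error,
visibly widening the PAD spread relative to the encoder-bypass path.  The
pipeline
therefore exposes a pass-through mode (`encoder = list(enabled = FALSE)`),
used both as an ablation and wherever the cleanest lesion-to-PAD channel is
needed.

## Age model

Gaussian-process regression of age on compact features plus a binary sex
column; prior mean = training mean age; isotropic squared-exponential
kernel plus white noise (rational-quadratic alternative available).
Hyperparameters (length-scale, signal SD, noise SD) maximize the log
marginal likelihood with analytic gradients, 3 seeded restarts initialized
around the median pairwise distance, and box bounds that keep the noise SD
above 1e-4 of the target SD (so noiseless data can be interpolated without
a singular kernel).  Everything is deterministic given the seed.

Evaluation is 10-fold cross-validation with a seeded random partition;
metrics (Pearson r, RMSE, MAE) are computed on the pooled out-of-fold
predictions, not averaged over folds.  PAD is exact arithmetic
(`predicted - chronological`), and no post-hoc PAD bias correction is
applied — out-of-sample PAD anticorrelates with age (regression to the
mean; r ~ -0.3 on the default suite), and that bias is handled where it
matters, by regressing age out of the downstream correlation analyses.
Note one scope limit of the cross-validation: the encoder and the feature
pipeline are fitted once on the full training cohort, so CV measures the
age-regression stage, not encoder generalization.

## Normative model

Per (tract, index) feature and per sex: the population mean is quadratic in
age (OLS on (1, a, a^2) with a = (age - 45)/10 for conditioning); the
population SD is an age-varying function fitted to the squared mean-model
residuals by a log-link Gamma GLM in (a, a^2), with the fitted variance
inflated by n/(n-3) to offset the mean model's degrees of freedom.  The
Gamma GLM is the maximum-likelihood variance-function estimator under
Gaussian errors; the more familiar regression of log |residual| was
evaluated and rejected because its per-cell dispersion
(SD ~ 1.11/sqrt(n), from Var[log|Z|] = pi^2/8) is too large to keep 532
simultaneous per-cell SD estimates inside a +/-10% band at any feasible
normative sample size.  A sliding-window alternative
(`method = "window"`: same-sex subjects within +/-10 years) is provided for
sensitivity analysis.  Queries outside the fitted age span raise an error;
there is no silent extrapolation.

z-scores are computed on the 532 weighted-average tract features (the same
grid as the attribution analysis), not on raw 100-step profiles.

**Calibration and sample sizes.**  The acceptance suite checks that z-scores
of 2000 held-out healthy subjects have per-cell mean within +/-0.1 and SD
within [0.9, 1.1] in *every* one of the 532 cells.  A simultaneous band over
532 cells needs roughly a 3.5-sigma margin, i.e. per-cell standard error
below ~0.027; the test-set contribution alone is 1/sqrt(2000) = 0.022, so
the normative draw must contribute well under that.  The calibration test
therefore fits the normative model on n = 4000 generated subjects (observed:
max |mean z| = 0.087, SD range [0.93, 1.07]).  A normative cohort of 524 —
the study-suite size used in the demo pipeline — cannot satisfy a
simultaneous band this tight; at that size only aggregate calibration is
asserted (mean calibration error shrinks monotonically over n in
{100, 524, 2000}).

## Group analyses

* **ANCOVA**: F test of the group factor on PAD adjusting for age, sex and
  handedness, via explicit model comparison; df = (g-1, n-g-3).  Post hoc
  pairwise tests are Welch by default (pooled optional) with Bonferroni
  multiplication by the number of pairs, capped at 1.
* **Mass-univariate deviation testing**: one-sample t per cell against 0,
  Benjamini-Hochberg adjustment across the 532 cells at q = 0.05 (Bonferroni
  optional — with 532 simultaneous cells it is severely conservative, which
  is why BH is the default).  Effect size is the one-sample standardized
  mean d = mean(z)/SD(z).  A cell that is exactly zero in every patient is
  "no deviation" (t = 0); a nonzero-constant cell is flagged undefined.
  Significant deviations are reported both as cells and as tracts
  (any-index-significant), since the two countings answer different
  questions.
* **Selection and attribution**: cells ranked by |d|, top
  ceiling(0.05 x 532) = 27 selected (ties broken by canonical feature
  order; restriction to significant cells first is an option).  PCA on the
  patients x selected-cells z matrix (centered, unscaled); PC1's sign is
  oriented so the PAD regression slope is positive; contributions are
  squared loadings normalized to 100% (absolute-loading normalization is an
  option — both sum to 100 and the choice is not decidable from published
  tables), summed per tract and per index.
* **Clinical correlations**: PAD and each clinical variable are
  residualized on age, sex and drug-class count by OLS; Pearson on the
  residuals if both residual vectors pass Shapiro-Wilk at 0.05, otherwise
  Spearman on residual ranks.  p-values use partial-correlation degrees of
  freedom (n - 2 - k).  An optional pre-filter excludes observations more
  than 2.5 SD from the variable mean (off by default; applied to the
  left-patient group in the demo, mirroring how outliers are handled in
  small patient samples).  Bootstrap 95% CIs are percentile intervals over
  seeded subject resamples with the correlation method frozen to the
  original-sample choice; degenerate resamples are skipped and counted,
  with a warning past 10%.

## Orchestration and reproducibility

`run_config()` collects every stage's parameters plus one global seed; all
stage seeds derive from it by fixed offsets, so a configuration determines
every artifact byte — rerunning the demo reproduces each CSV exactly.  Each
stage writes a JSON log embedding an MD5 hash of the configuration, and
downstream stages refuse artifacts produced under a different configuration
unless forced.  A thin command-line wrapper (`inst/scripts/tractage`)
exposes the stages as subcommands.

## Problem sizes used by the test and acceptance suites

Chosen once, as the package's own simulation design: the full study suite
(300/40/524/37/18/17) for the structural and prediction checks; normative
n = 4000 with 2000 held-out subjects for calibration; 200 replicates of 18
healthy "patients" for the null false-discovery rate; 100 replicates of 17
lesioned patients (severity 4, frequency coupling 1.2, diffuse 0.25) plus
37 fresh controls for lesion recovery and PAD power; 100 replicates with
frequency-dominated severity (intercept 2, coupling 2.0) through the
encoder-bypass model, with 400-draw bootstraps, for directional clinical
recovery.

## What the tests do and do not show

The generator emulates the statistical skeleton the analysis assumes: smooth
profiles, polynomial age trajectories, sex offsets, a shared biological-age
factor, homoscedastic Gaussian noise, deterministic lesion coupling.  It
does not emulate scanner effects, registration error, head motion,
non-Gaussian or age-heteroscedastic noise, spatially correlated noise along
tracts, or realistic inter-tract covariance beyond the single latent
factor.  Passing tests therefore demonstrate that the pipeline's statistics
do what they claim under their own assumptions, and that effect recovery
works when ground truth exists — not that the specific published effect
sizes would replicate on clinical data.  The paper-scale headline numbers on
real cohorts are context for realism checks, not reproduction targets.

## Known limitations

* The 76-tract registry is a plausible reconstruction of standard tract
  families, not an atlas release; only the names (and the count) matter to
  the code.
* The autoencoder's generalization gap is visible at this sample size
  (n = 300 vs ~191k parameters); the pass-through mode quantifies it.
* The normative model assumes quadratic-in-age means; strong non-polynomial
  trajectories (e.g. steep childhood maturation) would need the windowed
  method or a spline extension.
* Bootstrap CIs at n = 17 are wide; directional claims at that size need
  the strong-coupling regime the recovery tests use.
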