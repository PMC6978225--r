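# tractage

White matter brain age from along-tract diffusion profiles.

## The problem

Diffusion MRI tractometry summarizes a person's white matter as a
**connectogram**: seven scalar diffusion indices (GFA, AD, RD, MD, NG, NGO,
NGP) sampled at 100 normalized steps along 76 predefined tract bundles — a
76 × 100 × 7 array per subject.  Because these microstructural indices change
along stereotyped lifespan trajectories, a regression model trained on
healthy subjects can predict a **white matter brain age** from them.  The
**predicted age difference**

```
PAD = predicted age − chronological age
```

is an individual-level marker of accelerated (PAD > 0) or delayed white
matter aging, and is used to characterize patient groups — here, cohorts
emulating unilateral mesial temporal lobe epilepsy — and to relate apparent
brain aging to clinical variables (age of onset, duration of illness,
seizure frequency).

`tractage` implements the full analysis as a tested, reusable R pipeline for
researchers in neuroimaging-based biostatistics:

1. **Synthetic cohorts** — a seeded generator with smooth along-tract
   baselines, linear + quadratic age effects, sex offsets, a latent
   biological-age factor, and injectable tract-specific "lesions" whose
   severity is a known function of clinical covariates.  Every downstream
   stage is testable against ground truth without any imaging data.
2. **Feature pipeline** — along-tract Gaussian smoothing; per-step
   normalization frozen on the training cohort; per-step weights
   `w = −log10(p)` from the F test of an OLS fit on (age, age²); weighted
   averaging to 532 tract features (76 × 7).
3. **Encoder** — a single-hidden-layer sparse autoencoder (179 sigmoid
   units, MSE + KL sparsity + L2 loss, seeded full-batch L-BFGS)
   compressing 532 → 179 compact features, with a variance-explained
   reconstruction rate.
4. **Age model** — Gaussian-process regression (squared-exponential +
   noise kernel, marginal-likelihood hyperparameters) of age on compact
   features + sex; 10-fold cross-validation reporting r, RMSE, MAE; PAD.
5. **Normative model** — per tract × index and per sex, μ(age) by quadratic
   regression and σ(age) by a Gamma-GLM variance model; patient features
   become z-scores `z = (x − μ)/σ` against age- and sex-matched peers.
6. **Group analysis** — ANCOVA on PAD (covariates age, sex, handedness)
   with Welch/Bonferroni post hocs; mass-univariate one-sample t tests of
   z per cell with BH correction and effect sizes d = mean(z)/SD(z);
   top-5% (27-feature) selection; PCA attribution of PAD with tract/index
   contribution percentages; confound-adjusted Pearson/Spearman clinical
   correlations with bootstrap CIs.

## Worked example

The end-to-end demo simulates the six study cohorts (training n = 300,
testing n = 40, normative n = 524, controls/left/right patient groups
37/18/17), fits every stage, and writes artifacts plus a report:

```r
library(tractage)
summary <- run_end_to_end(run_config(seed = 42, outdir = "demo_run"))
```

or from a shell: `Rscript inst/scripts/tractage all --outdir demo_run --seed 42`.
With seed 42 this prints:

```
White matter brain age analysis report
======================================
compact feature dimension: 179
10-fold CV: r = 0.962, RMSE = 5.91 y, MAE = 4.62 y
residual-age correlation (training CV): r = -0.271

Group PAD means (years):
  controls   -0.09
  lmtle       4.07
  rmtle      14.18
ANCOVA group effect: F(2,66) = 11.222, p = 6.38e-05

Top contributing tracts (right-lateralized patient group):
  UF_R                      24.2%
  FS_OFC_R                  24.1%
  ILF_L                     19.0%
  IFOF_L                    15.8%
  PF_R                      12.3%

Clinical correlations (right-lateralized patient group):
  age_of_onset         pearson r = -0.097, p = 0.741
  duration_of_illness  pearson r = +0.733, p = 0.00288
  seizure_frequency    spearman r = +0.203, p = 0.485
```

Reading it: the 532 tract features were compressed to 179; cross-validated
age prediction is accurate to ~4.6 years; the mild negative residual–age
correlation is the expected regression-to-the-mean of a shrinkage
predictor.  The right-lateralized patient group — whose injected lesions
target the right uncinate fasciculus and neighboring temporal-lobe bundles,
with severity coupled to the clinical covariates — shows a strongly
elevated mean PAD, a significant ANCOVA group effect, and attribution that
correctly concentrates on the five injected tracts (UF_R first).  The
positive duration-of-illness correlation recovers the generator's coupling;
at n = 17 the per-variable correlations are noisy, which is exactly why the
recovery properties are asserted over 100 seeded replicates in the test
suite rather than on one draw.

## Layout

```
R/                  implementation (generator, IO, features, encoder,
                    age model, normative model, group analysis, pipeline)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
inst/scripts/tractage   command-line wrapper over the pipeline stages
vignettes/methods.Rmd   models, parameters, numerical choices, limitations
```

The methods vignette documents the generative model (and which features of
real data it does not emulate), every tunable parameter with units and
defaults, and the package's design decisions.
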