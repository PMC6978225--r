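Package: tractage
Title: White Matter Brain Age from Along-Tract Diffusion Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts white matter brain age from along-tract diffusion-index
    profiles ("connectograms": 76 tracts x 100 steps x 7 indices) and
    characterizes individual deviation from normative aging.  Provides a
    seeded synthetic-cohort generator with age, sex and lesion effects; a
    feature pipeline (along-tract Gaussian smoothing, per-step normalization
    frozen on the training cohort, age-association weighted averaging to 532
    tract features); a sparsity-regularized autoencoder compressing the
    features to a compact representation; Gaussian-process age regression
    with 10-fold cross-validation and predicted age difference (PAD) scores;
    an age- and sex-conditioned normative model yielding per-tract z-score
    deviation maps; and group-level analyses (ANCOVA with post hoc tests,
    mass-univariate deviation testing with effect sizes, PCA-based tract
    attribution of PAD, and confound-adjusted clinical correlations with
    bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    kernlab
Config/testthat/edition: 3
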