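# Shared fixtures, built lazily and cached for the whole test run.  The
# expensive objects (study suite, fitted pipeline, default autoencoder, age
# model, large normative fit) are built once and reused across test files.

ta_cache <- new.env(parent = emptyenv())

ta_get <- function(name, builder) {
  if (is.null(ta_cache[[name]])) ta_cache[[name]] <- builder()
  ta_cache[[name]]
}

# master seed for the fixture suite; all derived fixtures hang off it
TA_SEED <- 42L

ta_suite <- function() ta_get("suite", function() make_study_suite(TA_SEED))

ta_pipeline <- function() ta_get("pipeline", function() {
  s <- ta_suite()
  fit_feature_pipeline(s$training$connectograms, s$training$cohort$age)
})

ta_features <- function(name) {
  key <- paste0("features_", name)
  ta_get(key, function() pipeline_features(ta_suite()[[name]]$connectograms,
                                           ta_pipeline()))
}

ta_autoencoder <- function() ta_get("autoencoder", function() {
  train_autoencoder(ta_features("training"),
                    autoencoder_spec(seed = TA_SEED + 21L))
})

ta_encoded <- function(name) {
  key <- paste0("encoded_", name)
  ta_get(key, function() encode(ta_autoencoder(), ta_features(name)))
}

ta_age_model <- function() ta_get("age_model", function() {
  s <- ta_suite()
  train_age_model(ta_encoded("training"), s$training$cohort$sex,
                  s$training$cohort$age, age_model_spec(seed = TA_SEED + 22L))
})

# encoder-bypass (pass-through) age model: GP on the raw 532 features.
# Used by the ablation-style analyses that need the cleanest lesion -> PAD
# channel (no encoder generalization noise).
ta_age_model_passthrough <- function() ta_get("age_model_pt", function() {
  s <- ta_suite()
  train_age_model(ta_features("training"), s$training$cohort$sex,
                  s$training$cohort$age, age_model_spec(seed = TA_SEED + 22L))
})

ta_cv <- function() ta_get("cv", function() {
  s <- ta_suite()
  cross_validate_10fold(ta_encoded("training"), s$training$cohort$sex,
                        s$training$cohort$age,
                        age_model_spec(seed = TA_SEED + 22L),
                        seed = TA_SEED + 23L)
})

# large normative fit used by the calibration, null-FDR and lesion-recovery
# checks; 4000 subjects chosen so that the per-cell simultaneous z bands
# (532 cells) have adequate headroom (see the methods vignette)
ta_normative_big <- function() ta_get("normative_big", function() {
  cfg <- generator_config(n_subjects = 4000L, age_range = c(7, 92),
                          seed = TA_SEED * 131L + 31L)
  nf <- simulate_feature_cohort(cfg, ta_pipeline())
  fit_normative(nf$features, nf$cohort)
})

# prediction table for an arbitrary connectogram cohort through the cached
# pipeline + encoder + age model
ta_predict_cohort <- function(conns, cohort) {
  feats <- pipeline_features(conns, ta_pipeline())
  predict_age(ta_age_model(), encode(ta_autoencoder(), feats),
              cohort$sex, cohort$age, subject_ids = cohort$subject_id)
}

# a small deterministic connectogram with controllable values
ta_flat_connectogram <- function(value = 0.5, subject_id = "sub-001") {
  connectogram(array(value, c(76, 100, 7)), subject_id)
}

# uniform step weights (each profile averages its 100 steps)
ta_uniform_weights <- function() {
  w <- matrix(1 / 100, nrow = 532, ncol = 100,
              dimnames = list(feature_names(), NULL))
  structure(list(w = w, p = w * 0 + 1, F = w * 0, normalized = TRUE, n = 0L),
            class = "step_weights")
}
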