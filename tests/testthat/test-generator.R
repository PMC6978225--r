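test_that("noise-free generator with zero age effects returns baseline plus sex offset", {
  eff <- default_tract_effects()
  cfg <- generator_config(n_subjects = 2, subject_sd = 0, step_sd = 0,
                          brainage_sd = 0,
                          age_slopes = eff$slope * 0,
                          age_curvatures = eff$curvature * 0,
                          sex_ratio = 1, seed = 3)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$cohort$sex == "M"))
  for (cg in coh$connectograms)
    for (k in seq_len(7))
      expect_equal(unclass(cg)[, , k],
                   eff$baseline[, , k] + eff$sex_offset[, k],
                   tolerance = 0, ignore_attr = TRUE)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- generator_config(n_subjects = 3, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$connectograms, unclass),
                   lapply(b$connectograms, unclass))
  expect_identical(a$cohort, b$cohort)
})

test_that("a known age slope is recovered by OLS within 3 standard errors", {
  eff <- default_tract_effects()
  slopes <- eff$slope * 0
  slopes[5, 3] <- 0.01                       # one (tract, index) cell
  cfg <- generator_config(n_subjects = 300, subject_sd = 0.02,
                          step_sd = 0.05, brainage_sd = 0,
                          age_slopes = slopes,
                          age_curvatures = eff$curvature * 0,
                          sex_offsets = eff$sex_offset * 0, seed = 17)
  coh <- generate_cohort(cfg)
  cellmean <- vapply(coh$connectograms,
                     function(cg) mean(unclass(cg)[5, , 3]), numeric(1))
  fit <- summary(lm(cellmean ~ coh$cohort$age))
  est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 0.01), 3 * se)
})

test_that("empirical cell moments match configured moments at fixed age and sex", {
  cfg <- generator_config(n_subjects = 1000, subject_sd = 0.04,
                          step_sd = 0.07, brainage_sd = 0, seed = 23)
  coh <- generate_cohort(cfg, ages = rep(40, 1000), sexes = rep("F", 1000))
  eff <- default_tract_effects()
  v <- vapply(coh$connectograms, function(cg) unclass(cg)[10, 50, 2],
              numeric(1))
  mu_true <- eff$baseline[10, 50, 2] + eff$slope[10, 2] * (40 - 45) +
    eff$curvature[10, 2] * (40 - 45)^2
  sd_true <- sqrt(0.04^2 + 0.07^2)
  expect_lt(abs(mean(v) - mu_true), 3 * sd_true / sqrt(1000))
  expect_lt(abs(sd(v) - sd_true), 3 * sd_true / sqrt(2 * 1000))
})

test_that("generator configuration errors are raised", {
  expect_error(generator_config(age_range = c(50, 20)), "age_range")
  expect_error(generator_config(subject_sd = -1), "subject_sd")
  expect_error(generator_config(n_subjects = 0), "n_subjects")
})

test_that("lesion severity 0 leaves the connectogram untouched", {
  cfg <- generator_config(n_subjects = 1, seed = 5)
  cg <- generate_cohort(cfg)$connectograms[[1]]
  subj <- list(age_of_onset = 12.5, duration_of_illness = 25.5,
               seizure_frequency = 1.09)
  spec <- lesion_spec("UF_R", intercept = 0)
  out <- inject_lesion(cg, subj, spec, cfg)
  expect_identical(unclass(out)[, , ], unclass(cg)[, , ])
})

test_that("a purely focal lesion leaves the other 75 tracts bit-identical", {
  cfg <- generator_config(n_subjects = 1, seed = 6)
  cg <- generate_cohort(cfg)$connectograms[[1]]
  subj <- list(age_of_onset = 12.5, duration_of_illness = 25.5,
               seizure_frequency = 1.09)
  spec <- lesion_spec("UF_R", intercept = 2)    # diffuse_scale defaults to 0
  out <- inject_lesion(cg, subj, spec, cfg)
  keep <- setdiff(tract_registry(), "UF_R")
  expect_identical(unclass(out)[keep, , ], unclass(cg)[keep, , ])
  expect_false(identical(unclass(out)["UF_R", , "RD"],
                         unclass(cg)["UF_R", , "RD"]))
  expect_error(lesion_spec("NOT_A_TRACT"), "unknown tract")
})

test_that("realized lesion magnitude increases with seizure frequency", {
  spec <- lesion_spec("UF_R", intercept = 2, c_frequency = 1.5)
  freqs <- withr::with_seed(8, rgamma(17, shape = 0.7, rate = 0.64))
  sev <- vapply(freqs, function(f)
    lesion_severity(spec, list(age_of_onset = 12.5,
                               duration_of_illness = 25.5,
                               seizure_frequency = f)), numeric(1))
  expect_gt(cor(freqs, sev, method = "spearman"), 0)
})

test_that("study suite has the published cohort structure", {
  suite <- ta_suite()
  expect_identical(vapply(suite, function(x) nrow(x$cohort), integer(1)),
                   c(training = 300L, testing = 40L, normative = 524L,
                     controls = 37L, lmtle = 18L, rmtle = 17L))
  expect_gte(min(suite$normative$cohort$age), 7)
  expect_lte(max(suite$normative$cohort$age), 92)
  means <- vapply(suite[c("controls", "lmtle", "rmtle")],
                  function(x) mean(x$cohort$age), numeric(1))
  expect_lt(max(means) - min(means), 2)
  sexes <- vapply(suite[c("controls", "lmtle", "rmtle")],
                  function(x) sum(x$cohort$sex == "M"), numeric(1))
  expect_identical(unname(sexes), c(17, 10, 9))
  # clinical fields present iff patient group
  expect_true(all(!is.na(suite$rmtle$cohort$seizure_frequency)))
  expect_true(all(is.na(suite$controls$cohort$seizure_frequency)))
})
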