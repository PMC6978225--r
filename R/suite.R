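#' Default lesion specifications for the two patient-like groups
#'
#' The right-lateralized group receives the stronger alteration, targeting
#' the right uncinate fasciculus and the other temporal-lobe-associated
#' bundles most implicated in right-sided mesial temporal lobe epilepsy; the
#' left-lateralized group receives a mirrored, milder alteration.  Severity
#' couplings follow the directions reported clinically: earlier onset, longer
#' illness and more frequent seizures all mean more severe white matter
#' alteration in the right-lateralized group.
#'
#' @return A \code{\link{lesion_spec}}.
#' @export
default_rmtle_lesion <- function() {
  lesion_spec(c("UF_R", "FS_OFC_R", "IFOF_L", "ILF_L", "PF_R"),
              index_deltas = c(RD = 1, MD = 0.8, GFA = -0.6),
              intercept = 3, c_onset = -0.08, c_duration = 0.05,
              c_frequency = 0.8, diffuse_scale = 0.25)
}

#' @rdname default_rmtle_lesion
#' @export
default_lmtle_lesion <- function() {
  lesion_spec(c("UF_L", "FS_OFC_L", "IFOF_R", "ILF_R", "PF_L"),
              index_deltas = c(RD = 1, MD = 0.8, GFA = -0.6),
              intercept = 0.5, c_onset = 0.08, c_duration = -0.05,
              c_frequency = 0, diffuse_scale = 0.25)
}

# training-set age mixture: denser below 40 and above 60 than in between,
# as is typical of convenience lifespan samples
.suite_training_ages <- function(n) {
  u <- runif(n)
  ifelse(u < 0.49, runif(n, 18, 40),
         ifelse(u < 0.697, runif(n, 40, 60), runif(n, 60, 92)))
}

# deterministic proportional interleaving of sorted ages across groups,
# so that group mean ages match by construction
.matched_assignment <- function(n_per_group) {
  n <- sum(n_per_group)
  g <- length(n_per_group)
  assigned <- integer(g)
  out <- integer(n)
  for (i in seq_len(n)) {
    deficit <- n_per_group * i / n - assigned
    j <- which.max(deficit)
    out[i] <- j
    assigned[j] <- assigned[j] + 1L
  }
  out
}

.draw_clinical <- function(n, onset_mean, onset_sd, dur_mean, dur_sd,
                           freq_mean, freq_sd, aed_mean, aed_sd) {
  tnorm <- function(n, m, s, lo) pmax(lo, rnorm(n, m, s))
  shape <- (freq_mean / freq_sd)^2
  data.frame(
    age_of_onset        = tnorm(n, onset_mean, onset_sd, 1),
    duration_of_illness = tnorm(n, dur_mean, dur_sd, 1),
    seizure_frequency   = rgamma(n, shape = shape, rate = shape / freq_mean),
    n_aed_classes       = pmin(6, pmax(1, round(rnorm(n, aed_mean, aed_sd))))
  )
}

#' Generate the full synthetic study suite
#'
#' Builds the six cohorts the analysis pipeline expects: a training set
#' (n = 300, ages 18-92), an independent testing set (n = 40), a normative
#' set (n = 524, ages 7-92), and three study groups matched in age and sex by
#' construction: controls (n = 37), a left-lateralized patient group
#' (n = 18) and a right-lateralized patient group (n = 17).  Patient
#' connectograms receive tract-specific lesions whose severity is a
#' deterministic function of their drawn clinical covariates (age of onset,
#' duration of illness, seizure frequency); covariate moments follow the
#' published demographics of unilateral mesial temporal lobe epilepsy
#' cohorts.
#'
#' @param seed Integer master seed; every draw in the suite derives from it.
#' @param subject_sd,step_sd,brainage_sd Noise SDs passed to
#'   \code{\link{generator_config}} (defaults as documented there).
#' @param lesion_rmtle,lesion_lmtle \code{\link{lesion_spec}}s for the two
#'   patient groups; defaults \code{\link{default_rmtle_lesion}} /
#'   \code{\link{default_lmtle_lesion}}.
#' @return A named list of cohorts (\code{training}, \code{testing},
#'   \code{normative}, \code{controls}, \code{lmtle}, \code{rmtle}), each a
#'   list with \code{connectograms} and \code{cohort}.  The base generator
#'   config is attached as attribute \code{"config"} and the lesion specs as
#'   \code{"lesions"}.
#' @export
make_study_suite <- function(seed = 42L,
                             subject_sd = 0.03, step_sd = 0.06,
                             brainage_sd = 5,
                             lesion_rmtle = default_rmtle_lesion(),
                             lesion_lmtle = default_lmtle_lesion()) {
  seed <- as.integer(seed)
  # derived sub-seeds stay inside 32-bit integer range for any input seed
  base <- (seed %% 16000000L) * 131L
  base_cfg <- function(n, age_range, sub_seed) {
    generator_config(n_subjects = n, age_range = age_range,
                     subject_sd = subject_sd, step_sd = step_sd,
                     brainage_sd = brainage_sd, seed = base + sub_seed)
  }

  # ---- healthy cohorts -----------------------------------------------------
  tr_cfg <- base_cfg(300L, c(18, 92), 1L)
  tr_ages <- withr::with_seed(base + 11L, .suite_training_ages(300L))
  training <- generate_cohort(tr_cfg, ages = tr_ages, group = "train")

  te_cfg <- base_cfg(40L, c(18, 92), 2L)
  te_ages <- withr::with_seed(base + 12L, .suite_training_ages(40L))
  testing <- generate_cohort(te_cfg, ages = te_ages, group = "test")

  no_cfg <- base_cfg(524L, c(7, 92), 3L)
  normative <- generate_cohort(no_cfg, group = "normative")

  # ---- matched study groups ------------------------------------------------
  sizes <- c(controls = 37L, lmtle = 18L, rmtle = 17L)
  study <- withr::with_seed(base + 13L, {
    ages <- sort(pmin(60, pmax(22, rnorm(sum(sizes), 38.2, 8.2))))
    grp <- .matched_assignment(sizes)
    # shuffle order within the suite while keeping the matched assignment
    perm <- sample.int(length(ages))
    list(ages = ages[perm], grp = grp[perm])
  })
  sex_pool <- list(controls = c(rep("M", 17), rep("F", 20)),
                   lmtle = c(rep("M", 10), rep("F", 8)),
                   rmtle = c(rep("M", 9), rep("F", 8)))
  sex_pool <- lapply(sex_pool, function(s)
    withr::with_seed(base + 14L, sample(s)))

  build_group <- function(name, sub_seed) {
    k <- match(name, names(sizes))
    idx <- which(study$grp == k)
    cfg <- base_cfg(sizes[[name]], c(18, 92), sub_seed)
    generate_cohort(cfg, ages = study$ages[idx], sexes = sex_pool[[name]],
                    subject_ids = sprintf("%s-%03d", name,
                                          seq_len(sizes[[name]])),
                    group = name)
  }
  controls <- build_group("controls", 4L)
  lmtle    <- build_group("lmtle", 5L)
  rmtle    <- build_group("rmtle", 6L)

  # handedness (percent, right-dominant cohort) for the study groups
  hands <- withr::with_seed(base + 15L,
    pmin(100, pmax(-100, rnorm(sum(sizes), 90, 20))))
  controls$cohort$handedness <- hands[seq_len(37)]
  lmtle$cohort$handedness    <- hands[37 + seq_len(18)]
  rmtle$cohort$handedness    <- hands[55 + seq_len(17)]

  # clinical covariates (published cohort moments) and lesion injection
  lmtle$cohort[names(.clin_cols())] <- withr::with_seed(base + 16L,
    .draw_clinical(18L, 14.5, 5.6, 22.9, 7.7, 1.56, 1.73, 2.39, 1.33))
  rmtle$cohort[names(.clin_cols())] <- withr::with_seed(base + 17L,
    .draw_clinical(17L, 12.5, 6.7, 25.5, 9.3, 1.09, 1.31, 2.71, 0.69))

  lesion_group <- function(grp, spec, cfg) {
    sev <- numeric(nrow(grp$cohort))
    for (i in seq_along(grp$connectograms)) {
      grp$connectograms[[i]] <- inject_lesion(grp$connectograms[[i]],
                                              grp$cohort[i, ], spec, cfg)
      sev[i] <- attr(grp$connectograms[[i]], "severity")
    }
    grp$cohort$lesion_severity <- sev
    grp
  }
  lmtle <- lesion_group(lmtle, lesion_lmtle, base_cfg(1L, c(18, 92), 0L))
  rmtle <- lesion_group(rmtle, lesion_rmtle, base_cfg(1L, c(18, 92), 0L))

  suite <- list(training = training, testing = testing, normative = normative,
                controls = controls, lmtle = lmtle, rmtle = rmtle)
  attr(suite, "config") <- base_cfg(1L, c(18, 92), 0L)
  attr(suite, "lesions") <- list(rmtle = lesion_rmtle, lmtle = lesion_lmtle)
  attr(suite, "seed") <- seed
  suite
}

.clin_cols <- function() {
  c(age_of_onset = "age_of_onset", duration_of_illness = "duration_of_illness",
    seizure_frequency = "seizure_frequency", n_aed_classes = "n_aed_classes")
}

#' Combined cohort table of a study suite
#'
#' @param suite Output of \code{\link{make_study_suite}}.
#' @param cohorts Which cohorts to include.
#' @return One data frame with a row per subject.
#' @export
suite_cohort_table <- function(suite, cohorts = names(suite)) {
  cols <- c("subject_id", "age", "sex", "handedness", "group",
            "age_of_onset", "duration_of_illness", "seizure_frequency",
            "n_aed_classes")
  do.call(rbind, lapply(suite[cohorts], function(x) x$cohort[, cols]))
}
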