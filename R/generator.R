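#' Default per-cell generative effects
#'
#' The generator needs, for every (tract, index) cell, a smooth 100-step
#' baseline profile, a linear and a quadratic age coefficient, and an additive
#' sex offset.  Healthy along-tract profiles are emulated with a low-order
#' cosine series (smooth, non-constant, tract-specific), and age effects vary
#' across cells with roughly 30% of cells left flat so that age-association
#' weighting has genuine contrast to exploit.
#'
#' All constants are deterministic functions of the cell position via a
#' sine-hash (no RNG involved), so the "population" they define is a fixed
#' property of the package.  Index-level conventions follow the adult aging
#' literature qualitatively: anisotropy (GFA) and non-Gaussianity (NG, NGO,
#' NGP) decline with age, diffusivities (AD, RD, MD) rise.  Diffusivities are
#' in um^2/ms so that all seven indices live on a comparable O(0.1-2) scale.
#'
#' @return A list with elements \code{baseline} (76 x 100 x 7 array),
#'   \code{slope}, \code{curvature}, \code{sex_offset} (each 76 x 7 matrices;
#'   slope in index units per year at the reference age of 45),
#'   and \code{reference_age} (45).
#' @export
default_tract_effects <- function() {
  if (!is.null(.TA$effects)) return(.TA$effects)
  nt <- .TA$n_tracts; ni <- .TA$n_index; ns <- .TA$n_steps

  # deterministic pseudo-random field in [0,1), classic sine hash
  h <- function(t, k, salt) {
    x <- sin(outer(t * 12.9898, k * 78.233 + salt * 37.719, "+")) * 43758.5453
    x - floor(x)
  }
  tt <- seq_len(nt); kk <- seq_len(ni)

  base_level <- c(GFA = 0.45, AD = 1.60, RD = 0.55, MD = 0.90,
                  NG = 0.45, NGO = 0.35, NGP = 0.40)
  base_amp   <- c(GFA = 0.06, AD = 0.15, RD = 0.08, MD = 0.10,
                  NG = 0.06, NGO = 0.05, NGP = 0.05)
  slope_scale <- c(GFA = -0.0015, AD = 0.0020, RD = 0.0025, MD = 0.0020,
                   NG = -0.0010, NGO = -0.0008, NGP = -0.0012)
  curv_scale <- 2e-5       # per year^2, shared magnitude across indices
  sex_scale  <- 0.010      # additive shift for males, index units

  u1 <- h(tt, kk, 1); u2 <- h(tt, kk, 2); u3 <- h(tt, kk, 3)
  u4 <- h(tt, kk, 4); a1 <- h(tt, kk, 5); a2 <- h(tt, kk, 6)
  a3 <- h(tt, kk, 7); ph <- h(tt, kk, 8)

  informative <- u2 > 0.30                     # ~70% of cells carry age signal
  slope <- sweep(0.4 + 0.6 * u1, 2, slope_scale, "*") * informative
  curvature <- curv_scale * (2 * u3 - 1) * informative
  sex_offset <- sex_scale * (2 * u4 - 1)

  # smooth baselines: level + 3-term cosine series over normalized position
  x <- seq(0, 1, length.out = ns)
  baseline <- array(0, dim = c(nt, ns, ni))
  for (k in kk) {
    amp <- base_amp[k]
    for (t in tt) {
      baseline[t, , k] <- base_level[k] +
        amp * ((a1[t, k] - 0.5) * cos(pi * x + 2 * pi * ph[t, k]) +
               0.6 * (a2[t, k] - 0.5) * cos(2 * pi * x) +
               0.4 * (a3[t, k] - 0.5) * cos(3 * pi * x))
    }
  }
  dimnames(baseline) <- list(.TA$tracts, NULL, .TA$indices)
  dimnames(slope) <- dimnames(curvature) <- dimnames(sex_offset) <-
    list(.TA$tracts, .TA$indices)
  .TA$effects <- list(baseline = baseline, slope = slope,
                      curvature = curvature, sex_offset = sex_offset,
                      reference_age = 45)
  .TA$effects
}

#' Generator configuration
#'
#' Bundles everything \code{\link{generate_cohort}} needs to draw a cohort of
#' connectograms.  Per-cell effects default to
#' \code{\link{default_tract_effects}}.  The generative model for cell
#' (tract t, index k), subject i, step s is
#' \deqn{y = B_{tk}(s) + \beta_{tk} (b_i - 45) + \gamma_{tk} (b_i - 45)^2 +
#'       \delta_{tk}\,\mathrm{male}_i + u_{itk} + \epsilon_{itks}}
#' where \eqn{b_i = a_i + d_i} is the subject's latent "biological" brain age
#' (chronological age plus a subject-level deviation with SD
#' \code{brainage_sd}), \eqn{u} is a per-subject per-cell random intercept
#' (SD \code{subject_sd}) and \eqn{\epsilon} is step-level noise (SD
#' \code{step_sd}).  The biological-age deviation is what makes chronological
#' age imperfectly recoverable, giving the age model a realistic error floor.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param age_range Length-2 numeric, min < max, in years.
#' @param sex_ratio Fraction of males in (0, 1).
#' @param baseline_profiles 76 x 100 x 7 array of baselines.
#' @param age_slopes,age_curvatures,sex_offsets 76 x 7 coefficient matrices.
#' @param subject_sd Between-subject random-intercept SD (index units), >= 0.
#' @param step_sd Within-profile step noise SD (index units), >= 0.
#' @param brainage_sd SD (years) of the latent biological-age deviation, >= 0.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_subjects = 300L,
                             age_range = c(18, 92),
                             sex_ratio = 0.5,
                             baseline_profiles = NULL,
                             age_slopes = NULL,
                             age_curvatures = NULL,
                             sex_offsets = NULL,
                             subject_sd = 0.03,
                             step_sd = 0.06,
                             brainage_sd = 5,
                             seed = 1L) {
  eff <- default_tract_effects()
  if (is.null(baseline_profiles)) baseline_profiles <- eff$baseline
  if (is.null(age_slopes))        age_slopes        <- eff$slope
  if (is.null(age_curvatures))    age_curvatures    <- eff$curvature
  if (is.null(sex_offsets))       sex_offsets       <- eff$sex_offset

  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("configuration error: n_subjects must be >= 1")
  if (length(age_range) != 2L || !all(is.finite(age_range)) ||
      age_range[1] >= age_range[2])
    stop("configuration error: age_range must be [min, max] with min < max")
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("configuration error: sex_ratio must be in [0, 1]")
  for (nm in c("subject_sd", "step_sd", "brainage_sd"))
    if (get(nm) < 0) stop("configuration error: ", nm, " must be >= 0")
  stopifnot(identical(dim(baseline_profiles),
                      c(.TA$n_tracts, .TA$n_steps, .TA$n_index)),
            identical(dim(age_slopes), c(.TA$n_tracts, .TA$n_index)),
            identical(dim(age_curvatures), c(.TA$n_tracts, .TA$n_index)),
            identical(dim(sex_offsets), c(.TA$n_tracts, .TA$n_index)))

  structure(list(
    n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
    sex_ratio = sex_ratio, baseline_profiles = baseline_profiles,
    age_slopes = age_slopes, age_curvatures = age_curvatures,
    sex_offsets = sex_offsets, subject_sd = subject_sd, step_sd = step_sd,
    brainage_sd = brainage_sd, seed = as.integer(seed),
    reference_age = default_tract_effects()$reference_age
  ), class = "generator_config")
}

# flat (cell-major x step) expansions of the per-cell coefficients.
# cell order must match .TA$cell_tract / .TA$cell_index (tract outer,
# index inner); the baseline array is (tract, step, index).
.gen_flat_effects <- function(config) {
  nt <- .TA$n_tracts; ni <- .TA$n_index; ns <- .TA$n_steps
  # baseline in (step, index, tract) order -> s fastest, then k, then t
  base_flat <- as.vector(aperm(config$baseline_profiles, c(2L, 3L, 1L)))
  cellmat <- function(m) as.vector(t(m))  # (t,k) -> cell order t-outer
  list(
    base  = base_flat,
    slope = rep(cellmat(config$age_slopes), each = ns),
    curv  = rep(cellmat(config$age_curvatures), each = ns),
    sexo  = rep(cellmat(config$sex_offsets), each = ns)
  )
}

# core engine: given demographics, draw the flat n x 53200 value matrix.
# RNG state is the caller's responsibility.
.gen_value_matrix <- function(config, ages, male) {
  n <- length(ages)
  fl <- .gen_flat_effects(config)
  delta <- if (config$brainage_sd > 0) rnorm(n, 0, config$brainage_sd) else
    numeric(n)
  b <- ages + delta - config$reference_age
  M <- tcrossprod(rep(1, n), fl$base) +
    tcrossprod(b, fl$slope) + tcrossprod(b^2, fl$curv) +
    tcrossprod(as.numeric(male), fl$sexo)
  if (config$subject_sd > 0) {
    U <- matrix(rnorm(n * .TA$n_cells, 0, config$subject_sd), n, .TA$n_cells)
    M <- M + U[, rep(seq_len(.TA$n_cells), each = .TA$n_steps)]
  } else {
    # keep the RNG stream aligned across noise settings is not required;
    # draws are simply skipped when an SD is zero
  }
  if (config$step_sd > 0)
    M <- M + matrix(rnorm(length(M), 0, config$step_sd), n, ncol(M))
  attr(M, "brainage_delta") <- delta
  M
}

.gen_demographics <- function(config, ages = NULL, sexes = NULL,
                              subject_ids = NULL, group = "healthy") {
  n <- config$n_subjects
  if (is.null(ages))
    ages <- runif(n, config$age_range[1], config$age_range[2])
  if (is.null(sexes))
    sexes <- ifelse(runif(n) < config$sex_ratio, "M", "F")
  if (is.null(subject_ids))
    subject_ids <- sprintf("%s-%03d", group, seq_len(n))
  stopifnot(length(ages) == n, length(sexes) == n, all(sexes %in% c("M", "F")))
  data.frame(subject_id = subject_ids, age = ages, sex = sexes,
             handedness = NA_real_, group = group,
             age_of_onset = NA_real_, duration_of_illness = NA_real_,
             seizure_frequency = NA_real_, n_aed_classes = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate a cohort of synthetic connectograms
#'
#' Draws \code{config$n_subjects} connectograms under the generative model
#' described in \code{\link{generator_config}}, together with a cohort
#' metadata table.  Identical \code{config} (including seed) gives
#' bit-identical output.
#'
#' @param config A \code{\link{generator_config}}.
#' @param ages,sexes,subject_ids Optional overrides (e.g. to impose a matched
#'   age structure); when supplied they bypass the corresponding random draw.
#' @param group Group label written to the cohort table.
#' @return A list with \code{connectograms} (list of
#'   \code{\link{connectogram}}) and \code{cohort} (data frame of subject
#'   records, including the latent \code{brainage_delta} used to generate the
#'   data, kept for simulation diagnostics).
#' @examples
#' cfg <- generator_config(n_subjects = 3, seed = 7)
#' coh <- generate_cohort(cfg)
#' length(coh$connectograms)
#' @export
generate_cohort <- function(config, ages = NULL, sexes = NULL,
                            subject_ids = NULL, group = "healthy") {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    cohort <- .gen_demographics(config, ages, sexes, subject_ids, group)
    M <- .gen_value_matrix(config, cohort$age, cohort$sex == "M")
  })
  cohort$brainage_delta <- attr(M, "brainage_delta")
  rownames(M) <- cohort$subject_id
  list(connectograms = .matrix_to_cg_list(M), cohort = cohort)
}
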