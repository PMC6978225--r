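#' Lesion specification
#'
#' Describes a tract-specific disease alteration to inject into healthy
#' connectograms, providing ground truth for deviation-recovery analyses.
#' Each targeted tract's profile is shifted, per diffusion index, by
#' \code{index_deltas[k] * severity * healthy-population SD} of that cell,
#' where severity is a deterministic nonnegative function of the subject's
#' clinical covariates.  Default index directions mirror the epilepsy
#' literature: diffusivities up (RD most), anisotropy down.
#'
#' Severity is
#' \code{max(0, intercept + c_onset (onset - 12.5) + c_duration (duration -
#' 25.5) + c_frequency (freq - 1.09))}, i.e. coupling coefficients act on
#' covariates centered at typical patient values, so \code{intercept} is the
#' severity of a typical patient.
#'
#' @param target_tracts Character vector of tract names (must be in
#'   \code{\link{tract_registry}}).
#' @param index_deltas Named numeric vector of signed deltas in healthy-SD
#'   (z) units; names must be diffusion indices.  Indices not named get 0.
#' @param intercept,c_onset,c_duration,c_frequency Severity coupling
#'   coefficients (units: severity per year, per year, per seizure/month).
#' @param diffuse_scale Fraction in [0, 1) of the focal delta additionally
#'   applied to every non-target tract, emulating the widespread milder
#'   degeneration that accompanies a focal epileptic network.  The default 0
#'   keeps the lesion strictly local to \code{target_tracts}.
#' @return An object of class \code{"lesion_spec"}.
#' @export
lesion_spec <- function(target_tracts,
                        index_deltas = c(RD = 1, MD = 0.8, GFA = -0.6),
                        intercept = 1, c_onset = 0, c_duration = 0,
                        c_frequency = 0, diffuse_scale = 0) {
  unknown <- setdiff(target_tracts, .TA$tracts)
  if (length(unknown))
    stop("unknown tract name(s): ", paste(unknown, collapse = ", "))
  if (!all(names(index_deltas) %in% .TA$indices))
    stop("index_deltas names must be diffusion indices")
  deltas <- setNames(numeric(.TA$n_index), .TA$indices)
  deltas[names(index_deltas)] <- index_deltas
  if (diffuse_scale < 0 || diffuse_scale >= 1)
    stop("diffuse_scale must be in [0, 1)")
  structure(list(target_tracts = unique(target_tracts), index_deltas = deltas,
                 intercept = intercept, c_onset = c_onset,
                 c_duration = c_duration, c_frequency = c_frequency,
                 diffuse_scale = diffuse_scale),
            class = "lesion_spec")
}

#' Deterministic lesion severity for a subject
#'
#' @param spec A \code{\link{lesion_spec}}.
#' @param subject One-row data frame (or list) with \code{age_of_onset},
#'   \code{duration_of_illness}, \code{seizure_frequency}.
#' @return Nonnegative scalar severity.
#' @export
lesion_severity <- function(spec, subject) {
  stopifnot(inherits(spec, "lesion_spec"))
  vals <- c(subject$age_of_onset, subject$duration_of_illness,
            subject$seizure_frequency)
  if (length(vals) != 3L || anyNA(vals))
    stop("subject must carry complete clinical fields ",
         "(age_of_onset, duration_of_illness, seizure_frequency)")
  max(0, spec$intercept +
        spec$c_onset     * (subject$age_of_onset       - 12.5) +
        spec$c_duration  * (subject$duration_of_illness - 25.5) +
        spec$c_frequency * (subject$seizure_frequency   - 1.09))
}

# healthy-population marginal SD of a raw profile value per (tract, index)
# cell: subject random intercept plus step noise (age/sex are conditioned on).
.healthy_cell_sd <- function(config) {
  sqrt(config$subject_sd^2 + config$step_sd^2)
}

#' Inject a lesion into a connectogram
#'
#' Shifts each targeted tract's profile, per diffusion index, by
#' \code{delta * severity * healthy_sd}; all other tracts are returned
#' bit-identical.  The shift is constant along the 100 steps.
#'
#' @param cg A \code{\link{connectogram}}.
#' @param subject Subject record with clinical fields (see
#'   \code{\link{lesion_severity}}).
#' @param spec A \code{\link{lesion_spec}}.
#' @param config The \code{\link{generator_config}} the connectogram came
#'   from; supplies the healthy-population SD that scales z-unit deltas.
#' @return The lesioned \code{\link{connectogram}}; the realized severity is
#'   attached as attribute \code{"severity"}.
#' @export
inject_lesion <- function(cg, subject, spec, config) {
  stopifnot(inherits(cg, "connectogram"), inherits(spec, "lesion_spec"),
            inherits(config, "generator_config"))
  sev <- lesion_severity(spec, subject)
  vals <- unclass(cg)
  sdh <- .healthy_cell_sd(config)
  ti <- match(spec$target_tracts, .TA$tracts)
  shift <- spec$index_deltas * sev * sdh          # length 7, per index
  for (k in seq_len(.TA$n_index)) if (shift[k] != 0) {
    vals[ti, , k] <- vals[ti, , k] + shift[k]
    if (spec$diffuse_scale > 0)
      vals[-ti, , k] <- vals[-ti, , k] + spec$diffuse_scale * shift[k]
  }
  out <- connectogram(vals, attr(cg, "subject_id"))
  attr(out, "severity") <- sev
  out
}

# cells (feature-name level) a lesion spec actually perturbs
#' @rdname lesion_spec
#' @param spec A \code{\link{lesion_spec}}.
#' @export
lesion_cells <- function(spec) {
  idx <- names(spec$index_deltas)[spec$index_deltas != 0]
  as.vector(outer(spec$target_tracts, idx, paste, sep = "."))
}
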