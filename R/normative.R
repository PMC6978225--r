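#' Fit an age- and sex-conditioned normative model of tract features
#'
#' For every (tract, index) feature and each sex separately, fits the
#' population mean as a quadratic function of age by ordinary least squares,
#' and the population SD as a smooth function of age.  The default SD model
#' is a log-link Gamma regression of the squared mean-model residuals on
#' (age, age^2) — the maximum-likelihood variance-function estimator under
#' Gaussian errors — with the fitted variance inflated by n/(n - 3) to
#' offset the mean-model degrees of freedom.  A sliding-window alternative
#' (\code{method = "window"}: mean and SD of same-sex subjects within
#' +/- \code{window} years) is provided for sensitivity analysis.
#'
#' Queries outside the fitted age span raise an extrapolation error; there
#' is no silent extrapolation.
#'
#' @param features Subjects x 532 feature matrix of the normative cohort.
#' @param cohort Cohort table with \code{age} and \code{sex} for the same
#'   subjects (both sexes must be present).
#' @param method \code{"quadratic"} (default) or \code{"window"}.
#' @param window Half-width in years for the window method.
#' @return An object of class \code{"normative_params"}.
#' @export
fit_normative <- function(features, cohort, method = c("quadratic", "window"),
                          window = 10) {
  method <- match.arg(method)
  X <- as.matrix(features)
  stopifnot(nrow(X) == nrow(cohort))
  sexes <- sort(unique(cohort$sex))
  if (!setequal(sexes, c("F", "M")))
    stop("normative cohort must contain both sexes")
  span <- range(cohort$age)
  obj <- list(method = method, span = span, window = window,
              n = nrow(X), feature_names = colnames(X),
              age_center = 45, age_scale = 10)
  if (method == "window") {
    obj$age <- cohort$age
    obj$sex <- cohort$sex
    obj$features <- X
    class(obj) <- "normative_params"
    return(obj)
  }
  fits <- list()
  for (s in c("F", "M")) {
    idx <- cohort$sex == s
    a <- (cohort$age[idx] - obj$age_center) / obj$age_scale
    n <- sum(idx)
    if (n < 10L) stop("need at least 10 normative subjects per sex")
    D <- cbind(1, a, a^2)
    qrD <- qr(D)
    B <- qr.coef(qrD, X[idx, , drop = FALSE])        # 3 x 532
    R <- qr.resid(qrD, X[idx, , drop = FALSE])
    G <- .gamma_logvar_fit(D, R^2)                    # 3 x 532
    fits[[s]] <- list(mu = B, logvar = G,
                      var_inflation = n / (n - 3))
  }
  obj$fits <- fits
  class(obj) <- "normative_params"
  obj
}

# vectorized log-link Gamma IRLS for many responses sharing one design.
# For the log link the working weight is constant, so each iteration is a
# single least-squares solve of the working response.
.gamma_logvar_fit <- function(D, Y2, maxit = 50L, tol = 1e-10) {
  Y2 <- pmax(Y2, 1e-300)
  qrD <- qr(D)
  B <- qr.coef(qrD, log(Y2))          # init: log-residual regression
  for (it in seq_len(maxit)) {
    eta <- D %*% B
    mu <- exp(eta)
    Znew <- eta + (Y2 - mu) / mu
    Bnew <- qr.coef(qrD, Znew)
    if (max(abs(Bnew - B)) < tol) { B <- Bnew; break }
    B <- Bnew
  }
  B
}

# mu and sigma for one sex at given ages: returns list of (n x 532) matrices
.normative_musd <- function(params, ages, sex) {
  if (any(ages < params$span[1] - 1e-9 | ages > params$span[2] + 1e-9))
    stop(sprintf("extrapolation error: query age outside fitted span [%.1f, %.1f]",
                 params$span[1], params$span[2]))
  if (params$method == "window") {
    mu <- matrix(NA_real_, length(ages), ncol(params$features))
    sd <- mu
    for (i in seq_along(ages)) {
      sel <- params$sex == sex & abs(params$age - ages[i]) <= params$window
      if (sum(sel) < 10L)
        stop("window method: fewer than 10 normative subjects near age ",
             round(ages[i], 1))
      mu[i, ] <- colMeans(params$features[sel, , drop = FALSE])
      sd[i, ] <- apply(params$features[sel, , drop = FALSE], 2, stats::sd)
    }
    return(list(mu = mu, sd = sd))
  }
  f <- params$fits[[sex]]
  a <- (ages - params$age_center) / params$age_scale
  D <- cbind(1, a, a^2)
  mu <- D %*% f$mu
  sd <- sqrt(exp(D %*% f$logvar) * f$var_inflation)
  list(mu = mu, sd = sd)
}

#' Normative z-scores for one subject
#'
#' Transforms a subject's 532 tract features into deviation z-scores against
#' the age- and sex-matched normative population:
#' \code{z = (x - mu(age, sex)) / sigma(age, sex)} per (tract, index) cell.
#' A larger |z| means a larger deviation from the matched population.
#'
#' @param features Named length-532 feature vector.
#' @param subject Subject record (needs \code{age}, \code{sex}).
#' @param params A \code{"normative_params"} object.
#' @return 76 x 7 matrix of z-scores (tracts x indices).
#' @export
zscore_subject <- function(features, subject, params) {
  stopifnot(inherits(params, "normative_params"))
  z <- zscore_cohort(matrix(features, nrow = 1,
                            dimnames = list(NULL, names(features))),
                     data.frame(age = subject$age, sex = subject$sex),
                     params)[1, ]
  matrix(z, nrow = .TA$n_tracts, ncol = .TA$n_index, byrow = TRUE,
         dimnames = list(.TA$tracts, .TA$indices))
}

#' Normative z-scores for a cohort
#'
#' @param features Subjects x 532 matrix.
#' @param cohort Table with \code{age}, \code{sex} per subject.
#' @param params A \code{"normative_params"} object.
#' @return Subjects x 532 matrix of z-scores.
#' @export
zscore_cohort <- function(features, cohort, params) {
  stopifnot(inherits(params, "normative_params"))
  X <- as.matrix(features)
  Z <- matrix(NA_real_, nrow(X), ncol(X),
              dimnames = list(rownames(X), colnames(X)))
  for (s in c("F", "M")) {
    idx <- which(cohort$sex == s)
    if (!length(idx)) next
    ms <- .normative_musd(params, cohort$age[idx], s)
    Z[idx, ] <- (X[idx, , drop = FALSE] - ms$mu) / ms$sd
  }
  Z
}

#' Invert z-scores back to feature values (round-trip check)
#' @inheritParams zscore_cohort
#' @param z Subjects x 532 z-score matrix.
#' @export
unzscore_cohort <- function(z, cohort, params) {
  Z <- as.matrix(z)
  X <- matrix(NA_real_, nrow(Z), ncol(Z),
              dimnames = list(rownames(Z), colnames(Z)))
  for (s in c("F", "M")) {
    idx <- which(cohort$sex == s)
    if (!length(idx)) next
    ms <- .normative_musd(params, cohort$age[idx], s)
    X[idx, ] <- Z[idx, , drop = FALSE] * ms$sd + ms$mu
  }
  X
}
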