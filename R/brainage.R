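#' Age model specification
#'
#' Gaussian-process regression of chronological age on compact features plus
#' a binary sex column.  The default kernel is an isotropic squared
#' exponential plus white noise,
#' \deqn{k(x, x') = \sigma_f^2 \exp(-\|x - x'\|^2 / (2\ell^2)) +
#'       \sigma_n^2 \delta_{xx'},}
#' with hyperparameters \eqn{(\ell, \sigma_f, \sigma_n)} fitted by seeded
#' maximization of the log marginal likelihood with \code{n_restarts}
#' restarts; a rational-quadratic alternative (shape fixed at 2) is
#' available.  The prior mean is the training mean age.
#'
#' @param kernel \code{"squared_exponential_plus_noise"} or
#'   \code{"rational_quadratic_plus_noise"}.
#' @param n_restarts Number of optimizer restarts (>= 1).
#' @param seed Integer seed for the restarts.
#' @return An object of class \code{"age_model_spec"}.
#' @export
age_model_spec <- function(kernel = c("squared_exponential_plus_noise",
                                      "rational_quadratic_plus_noise"),
                           n_restarts = 3L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  structure(list(kernel = kernel, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "age_model_spec")
}

.gp_sqdist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D, 0)
}

.gp_kern <- function(D2, theta, kernel) {
  ell2 <- exp(2 * theta[1]); sf2 <- exp(2 * theta[2])
  if (kernel == "squared_exponential_plus_noise")
    sf2 * exp(-D2 / (2 * ell2))
  else
    sf2 * (1 + D2 / (2 * 2 * ell2))^(-2)   # rational quadratic, alpha = 2
}

# negative log marginal likelihood and gradient in
# theta = (log ell, log sigma_f, log sigma_n)
.gp_nlml <- function(theta, D2, y, kernel, grad = FALSE) {
  n <- length(y)
  sn2 <- exp(2 * theta[3])
  K <- .gp_kern(D2, theta, kernel)
  Ky <- K + diag(sn2, n)
  L <- tryCatch(chol(Ky), error = function(e) NULL)
  if (is.null(L)) return(if (grad) list(value = 1e10, grad = c(0, 0, 0))
                         else 1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  val <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  if (!grad) return(val)
  Kinv <- chol2inv(L)
  W <- Kinv - tcrossprod(alpha)      # d(nlml)/dK = W / 2
  ell2 <- exp(2 * theta[1])
  if (kernel == "squared_exponential_plus_noise") {
    dK_ell <- K * D2 / ell2
  } else {
    base <- 1 + D2 / (4 * ell2)
    dK_ell <- exp(2 * theta[2]) * 2 * base^(-3) * (D2 / (2 * ell2))
  }
  g <- c(0.5 * sum(W * dK_ell),
         0.5 * sum(W * (2 * K)),
         0.5 * sum(diag(W)) * 2 * sn2)
  list(value = val, grad = g)
}

#' Train the Gaussian-process age model
#'
#' @param features Subjects x d matrix of compact features.
#' @param sex Character (M/F) or 0/1 numeric vector; encoded as one binary
#'   column appended to the features.
#' @param ages Chronological ages in years (non-constant).
#' @param spec An \code{\link{age_model_spec}}.
#' @return An object of class \code{"age_model"}.
#' @export
train_age_model <- function(features, sex, ages, spec = age_model_spec()) {
  stopifnot(inherits(spec, "age_model_spec"))
  X <- cbind(as.matrix(features), sex = .encode_sex(sex))
  if (!all(is.finite(X))) stop("non-finite features")
  n <- nrow(X)
  if (n < 20L) stop("need at least 20 subjects")
  if (length(ages) != n) stop("ages must match rows of features")
  if (stats::sd(ages) == 0) stop("degenerate target: ages are constant")

  ybar <- mean(ages)
  y <- ages - ybar
  D2 <- .gp_sqdist(X)
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (med == 0) med <- 1
  sdy <- stats::sd(y)
  lower <- c(log(med) - 6, log(sdy) - 6, log(sdy * 1e-4))
  upper <- c(log(med) + 6, log(sdy) + 4, log(sdy * 2))

  inits <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_restarts), function(i) {
      jit <- stats::runif(3, -0.5, 0.5)
      c(log(med * c(0.5, 1, 2)[(i - 1) %% 3 + 1]), log(sdy),
        log(sdy * 0.3)) + jit
    })
  })
  best <- NULL
  for (th0 in inits) {
    fit <- stats::optim(th0,
                        fn = function(th) .gp_nlml(th, D2, y, spec$kernel),
                        gr = function(th) .gp_nlml(th, D2, y, spec$kernel,
                                                   grad = TRUE)$grad,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = 200))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  K <- .gp_kern(D2, theta, spec$kernel) + diag(exp(2 * theta[3]), n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  structure(list(spec = spec, X = X, y_mean = ybar, alpha = alpha,
                 theta = theta, nlml = best$value,
                 hyperparameters = c(lengthscale = exp(theta[1]),
                                     signal_sd = exp(theta[2]),
                                     noise_sd = exp(theta[3]))),
            class = "age_model")
}

.encode_sex <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    if (!all(sex %in% c("M", "F"))) stop("sex must be 'M'/'F' or 0/1")
    as.numeric(sex == "M")
  } else as.numeric(sex)
}

#' Predict white matter brain age and PAD
#'
#' Posterior-mean predictions; the predicted age difference is defined as
#' \code{pad = predicted_age - chronological_age}, exact arithmetic, no
#' rounding.
#'
#' @param model A trained \code{"age_model"}.
#' @param features Subjects x d matrix of compact features.
#' @param sex Sex vector (M/F or 0/1).
#' @param ages Chronological ages (years).
#' @param subject_ids Optional ids for the output table.
#' @return Data frame with \code{subject_id}, \code{chronological_age},
#'   \code{predicted_age}, \code{pad}.
#' @export
predict_age <- function(model, features, sex, ages, subject_ids = NULL) {
  stopifnot(inherits(model, "age_model"))
  Xs <- cbind(as.matrix(features), sex = .encode_sex(sex))
  if (ncol(Xs) != ncol(model$X))
    stop("dimension mismatch: expected ", ncol(model$X), " columns")
  Ks <- .gp_kern(.gp_sqdist(Xs, model$X), model$theta, model$spec$kernel)
  pred <- as.vector(Ks %*% model$alpha) + model$y_mean
  if (is.null(subject_ids))
    subject_ids <- rownames(features) %||% sprintf("s%03d", seq_along(pred))
  data.frame(subject_id = subject_ids, chronological_age = ages,
             predicted_age = pred, pad = pred - ages,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction accuracy metrics
#'
#' Pearson correlation, root-mean-square error and mean absolute error
#' between chronological and predicted age.
#'
#' @param chronological,predicted Numeric vectors (years).
#' @return List with \code{r}, \code{rmse}, \code{mae}.
#' @export
model_metrics <- function(chronological, predicted) {
  err <- predicted - chronological
  list(r = stats::cor(chronological, predicted),
       rmse = sqrt(mean(err^2)), mae = mean(abs(err)))
}

#' 10-fold cross-validation of the age model
#'
#' Seeded random partition of the subjects into 10 folds of near-equal size;
#' each fold is predicted by a model trained on the other nine, and the
#' metrics are computed on the pooled out-of-fold predictions.
#'
#' @param features,sex,ages As in \code{\link{train_age_model}}.
#' @param spec An \code{\link{age_model_spec}}.
#' @param seed Integer seed for the fold assignment.
#' @param k Number of folds (default 10).
#' @return List with \code{metrics} (see \code{\link{model_metrics}}),
#'   \code{predictions} (pooled out-of-fold prediction table) and
#'   \code{folds} (fold assignment).
#' @export
cross_validate_10fold <- function(features, sex, ages,
                                  spec = age_model_spec(), seed = 1L,
                                  k = 10L) {
  n <- length(ages)
  if (n < k) stop("need at least ", k, " subjects for ", k, "-fold CV")
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  sexn <- .encode_sex(sex)
  X <- as.matrix(features)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    m <- train_age_model(X[!hold, , drop = FALSE], sexn[!hold], ages[!hold],
                         spec)
    pred[hold] <- predict_age(m, X[hold, , drop = FALSE], sexn[hold],
                              ages[hold])$predicted_age
  }
  res <- data.frame(subject_id = rownames(X) %||% sprintf("s%03d", 1:n),
                    chronological_age = ages, predicted_age = pred,
                    pad = pred - ages, fold = folds,
                    stringsAsFactors = FALSE)
  list(metrics = model_metrics(ages, pred), predictions = res, folds = folds)
}

#' Correlation between prediction residuals and age
#'
#' Pearson correlation between PAD (predicted minus chronological age) and
#' chronological age.  Shrinkage predictors regress toward the mean age, so
#' this correlation is typically negative.
#'
#' @param results Prediction table from \code{\link{predict_age}} or
#'   \code{\link{cross_validate_10fold}}.
#' @return Scalar Pearson r.
#' @export
residual_age_correlation <- function(results) {
  if (nrow(results) < 3L) stop("need at least 3 subjects")
  if (stats::sd(results$pad) == 0)
    stop("undefined correlation: PAD is constant")
  stats::cor(results$pad, results$chronological_age)
}
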