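#' Autoencoder specification
#'
#' A single-hidden-layer autoencoder compresses the 532 tract features to a
#' compact representation (default 179 units).  The loss is reconstruction
#' mean squared error plus a Kullback-Leibler sparsity penalty that pushes
#' the mean activation of each hidden unit toward \code{sparsity_target},
#' plus an L2 weight penalty.  Hidden units are sigmoid (the sparsity
#' penalty only applies to sigmoid activations); the output layer is linear;
#' inputs are column-standardized on the training set and the
#' standardization is frozen.  Training is full-batch deterministic
#' quasi-Newton (L-BFGS), seeded, for up to \code{epochs} iterations.
#'
#' @param hidden_units Encoded dimension, 1 <= hidden_units < 532.
#' @param epochs Maximum optimizer iterations (>= 1).
#' @param sparsity_target Target mean hidden activation in (0, 1).
#' @param sparsity_weight Weight of the KL sparsity penalty (>= 0).
#' @param l2_weight Weight of the L2 penalty (>= 0).
#' @param seed Integer seed for weight initialization.
#' @param activation \code{"sigmoid"} (default) or \code{"linear"}.
#' @return An object of class \code{"autoencoder_spec"}.
#' @export
autoencoder_spec <- function(hidden_units = 179L, epochs = 1600L,
                             sparsity_target = 0.05, sparsity_weight = 1,
                             l2_weight = 1e-4, seed = 1L,
                             activation = c("sigmoid", "linear")) {
  activation <- match.arg(activation)
  if (hidden_units < 1L || hidden_units >= .TA$n_cells)
    stop("hidden_units must be in [1, 531]")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (sparsity_target <= 0 || sparsity_target >= 1)
    stop("sparsity_target must be in (0, 1)")
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight, l2_weight = l2_weight,
                 seed = as.integer(seed), activation = activation),
            class = "autoencoder_spec")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.ae_unpack <- function(theta, d, h) {
  i1 <- d * h; i2 <- i1 + h; i3 <- i2 + h * d
  list(W1 = matrix(theta[1:i1], d, h),
       b1 = theta[(i1 + 1):i2],
       W2 = matrix(theta[(i2 + 1):i3], h, d),
       b2 = theta[(i3 + 1):(i3 + d)])
}

# loss and gradient on standardized inputs X (n x d)
.ae_objective <- function(theta, X, spec) {
  n <- nrow(X); d <- ncol(X); h <- spec$hidden_units
  p <- .ae_unpack(theta, d, h)
  A <- sweep(X %*% p$W1, 2, p$b1, "+")
  Z <- if (spec$activation == "sigmoid") .sigmoid(A) else A
  E <- sweep(Z %*% p$W2, 2, p$b2, "+") - X
  J <- sum(E^2) / (2 * n) +
    spec$l2_weight / 2 * (sum(p$W1^2) + sum(p$W2^2))
  rho <- spec$sparsity_target
  if (spec$activation == "sigmoid" && spec$sparsity_weight > 0) {
    rhat <- pmin(1 - 1e-12, pmax(1e-12, colMeans(Z)))
    J <- J + spec$sparsity_weight *
      sum(rho * log(rho / rhat) + (1 - rho) * log((1 - rho) / (1 - rhat)))
  }
  En <- E / n
  gW2 <- crossprod(Z, En) + spec$l2_weight * p$W2
  gb2 <- colSums(En)
  dZ <- En %*% t(p$W2)
  if (spec$activation == "sigmoid" && spec$sparsity_weight > 0)
    dZ <- sweep(dZ, 2, spec$sparsity_weight *
                  (-rho / rhat + (1 - rho) / (1 - rhat)) / n, "+")
  dA <- if (spec$activation == "sigmoid") dZ * Z * (1 - Z) else dZ
  gW1 <- crossprod(X, dA) + spec$l2_weight * p$W1
  gb1 <- colSums(dA)
  list(value = J, grad = c(gW1, gb1, gW2, gb2))
}

#' Train the sparse autoencoder
#'
#' @param features Numeric matrix, subjects x 532 features (>= 2 subjects).
#' @param spec An \code{\link{autoencoder_spec}}.
#' @return An object of class \code{"autoencoder"} carrying the frozen
#'   column standardization, the weights, and a training report with
#'   \code{reconstruction_rate} (percent of training variance explained by
#'   the reconstruction, on the standardized scale), \code{final_loss} and
#'   \code{converged}.
#' @export
train_autoencoder <- function(features, spec = autoencoder_spec()) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance feature matrix: ",
         paste(utils::head(colnames(X)[scl == 0], 5), collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  d <- ncol(Xs); h <- spec$hidden_units
  r <- sqrt(6 / (d + h))
  theta0 <- withr::with_seed(spec$seed,
    c(stats::runif(d * h, -r, r), rep(0, h),
      stats::runif(h * d, -r, r), rep(0, d)))

  # optim evaluates fn and gr at the same point; cache the last objective
  memo <- new.env()
  obj_at <- function(th) {
    if (is.null(memo$th) || !identical(th, memo$th)) {
      memo$o <- .ae_objective(th, Xs, spec)
      memo$th <- th
    }
    memo$o
  }
  fit <- stats::optim(theta0,
                      fn = function(th) obj_at(th)$value,
                      gr = function(th) obj_at(th)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = spec$epochs, factr = 10))
  if (!all(is.finite(fit$par)) || !is.finite(fit$value))
    stop("divergence error: non-finite loss after ", fit$counts[1],
         " evaluations (loss = ", fit$value, ")")
  p <- .ae_unpack(fit$par, d, h)
  model <- structure(list(spec = spec, center = ctr, scale = scl,
                          W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
                          feature_names = colnames(X)),
                     class = "autoencoder")
  rate <- reconstruction_rate(model, X)
  model$report <- list(reconstruction_rate = rate, final_loss = fit$value,
                       converged = fit$convergence == 0,
                       evaluations = unname(fit$counts[1]))
  model
}

#' Encode features into the compact representation
#'
#' @param model A trained \code{"autoencoder"}.
#' @param features Subjects x 532 matrix (same feature registry as training).
#' @return Subjects x \code{hidden_units} matrix of compact features.
#' @export
encode <- function(model, features) {
  stopifnot(inherits(model, "autoencoder"))
  X <- as.matrix(features)
  if (ncol(X) != length(model$center))
    stop("dimension mismatch: expected ", length(model$center), " features")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  A <- sweep(Xs %*% model$W1, 2, model$b1, "+")
  Z <- if (model$spec$activation == "sigmoid") .sigmoid(A) else A
  rownames(Z) <- rownames(X)
  colnames(Z) <- sprintf("c%03d", seq_len(ncol(Z)))
  Z
}

#' Decode compact features back to the feature space
#' @param model A trained \code{"autoencoder"}.
#' @param compact Subjects x \code{hidden_units} matrix.
#' @return Subjects x 532 matrix on the original feature scale.
#' @export
decode <- function(model, compact) {
  stopifnot(inherits(model, "autoencoder"))
  Z <- as.matrix(compact)
  if (ncol(Z) != model$spec$hidden_units)
    stop("dimension mismatch: expected ", model$spec$hidden_units, " columns")
  Xs <- sweep(Z %*% model$W2, 2, model$b2, "+")
  out <- sweep(sweep(Xs, 2, model$scale, "*"), 2, model$center, "+")
  colnames(out) <- model$feature_names
  out
}

#' Reconstruction rate (percent variance explained)
#'
#' \code{100 * (1 - sum((x - xhat)^2) / sum((x - xbar)^2))}, computed on the
#' standardized feature scale.
#'
#' @param model A trained \code{"autoencoder"}.
#' @param features Subjects x 532 matrix.
#' @return Scalar percent (<= 100).
#' @export
reconstruction_rate <- function(model, features) {
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xhat <- sweep(encode(model, X) %*% model$W2, 2, model$b2, "+")
  tss <- sum(sweep(Xs, 2, colMeans(Xs))^2)
  100 * (1 - sum((Xs - Xhat)^2) / tss)
}
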