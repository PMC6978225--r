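#' Feature preprocessing parameters
#'
#' Controls the three-stage reduction of a connectogram to 532 tract
#' features: (1) along-tract Gaussian smoothing, (2) per-step normalization
#' against training-cohort statistics, (3) age-association-weighted
#' averaging over the 100 steps of each (tract, index) profile.
#'
#' @param smooth_sigma SD of the 1-D Gaussian kernel in step units (>= 0;
#'   0 disables smoothing).  Default 2 steps.
#' @param kernel_truncation Kernel support in multiples of sigma (default 3).
#' @param boundary_mode Edge handling for the convolution: \code{"reflect"}
#'   (mirror, edge sample included) or \code{"nearest"} (edge replication).
#' @param pvalue_floor Smallest admissible p-value in the weighting stage;
#'   caps raw weights at \code{-log10(pvalue_floor)}.
#' @param normalize_weights Renormalize each profile's 100 weights to sum 1
#'   so the reduction is a true weighted mean (default TRUE).
#' @return An object of class \code{"preprocess_params"}.
#' @export
preprocess_params <- function(smooth_sigma = 2, kernel_truncation = 3,
                              boundary_mode = c("reflect", "nearest"),
                              pvalue_floor = 1e-300,
                              normalize_weights = TRUE) {
  boundary_mode <- match.arg(boundary_mode)
  if (smooth_sigma < 0)
    stop("configuration error: smooth_sigma must be >= 0")
  if (pvalue_floor <= 0 || pvalue_floor >= 1)
    stop("configuration error: pvalue_floor must be in (0, 1)")
  structure(list(smooth_sigma = smooth_sigma,
                 kernel_truncation = kernel_truncation,
                 boundary_mode = boundary_mode,
                 pvalue_floor = pvalue_floor,
                 normalize_weights = normalize_weights),
            class = "preprocess_params")
}

# n x n convolution matrix for one profile; rows sum to 1, so constants are
# preserved exactly and sigma = 0 is the identity.
.smoothing_matrix <- function(sigma, truncation = 3,
                              boundary = "reflect", n = .TA$n_steps) {
  if (sigma == 0) return(diag(n))
  r <- max(1L, ceiling(truncation * sigma))
  j <- -r:r
  g <- exp(-j^2 / (2 * sigma^2))
  g <- g / sum(g)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + j
    if (boundary == "reflect") {
      repeat {
        below <- idx < 1L; above <- idx > n
        if (!any(below | above)) break
        idx[below] <- 1L - idx[below]
        idx[above] <- 2L * n + 1L - idx[above]
      }
    } else {
      idx <- pmin(n, pmax(1L, idx))
    }
    for (m in seq_along(idx)) S[i, idx[m]] <- S[i, idx[m]] + g[m]
  }
  S
}

# flat-matrix smoothing: every 100-column cell block right-multiplied by t(S)
.smooth_matrix_rows <- function(M, S) {
  n <- nrow(M); ns <- .TA$n_steps; nc <- .TA$n_cells
  # columns of A are individual profiles (step fastest in flat layout)
  A <- matrix(t(M), nrow = ns)          # ns x (nc * n)
  A <- S %*% A
  matrix(as.vector(A), nrow = n, byrow = TRUE,
         dimnames = list(rownames(M), NULL))
}

#' Smooth along-tract profiles
#'
#' Convolves each of the 532 per-cell 100-step profiles with a normalized
#' discrete Gaussian kernel.  The kernel preserves constants (its rows sum
#' to 1 after boundary folding) and \code{smooth_sigma = 0} returns the
#' input unchanged.
#'
#' @param cg A \code{\link{connectogram}}.
#' @param params A \code{\link{preprocess_params}}.
#' @return A smoothed \code{\link{connectogram}}.
#' @export
smooth_profiles <- function(cg, params = preprocess_params()) {
  stopifnot(inherits(cg, "connectogram"), inherits(params, "preprocess_params"))
  S <- .smoothing_matrix(params$smooth_sigma, params$kernel_truncation,
                         params$boundary_mode)
  row <- .cg_to_row(cg)
  sm <- .smooth_matrix_rows(matrix(row, nrow = 1), S)
  .row_to_cg(sm[1, ], attr(cg, "subject_id"))
}

#' Fit per-step normalization statistics on a training cohort
#'
#' Computes, for every (tract, step, index) cell, the sample mean and sample
#' SD (n - 1 denominator) over the training subjects.  Cells whose SD is
#' exactly zero are flagged degenerate; normalizing through a degenerate cell
#' is an error unless an epsilon substitution is configured.
#'
#' @param training List of \code{\link{connectogram}}s (>= 2 subjects).
#' @return An object of class \code{"norm_stats"} with fields \code{mean},
#'   \code{sd} (length-53200 vectors in flat layout), \code{degenerate}
#'   (logical), \code{n}.
#' @export
fit_step_normalization <- function(training) {
  M <- if (is.matrix(training)) training else .cg_list_to_matrix(training)
  if (nrow(M) < 2L) stop("need at least 2 training subjects")
  mu <- colMeans(M)
  sd <- sqrt(colSums(sweep(M, 2, mu)^2) / (nrow(M) - 1))
  structure(list(mean = mu, sd = sd, degenerate = sd == 0, n = nrow(M)),
            class = "norm_stats")
}

.apply_norm_matrix <- function(M, stats, epsilon = NULL) {
  sd <- stats$sd
  if (any(stats$degenerate)) {
    if (is.null(epsilon))
      stop(sprintf("degenerate cell: %d cell-step(s) have zero training SD; supply 'epsilon' to substitute",
                   sum(stats$degenerate)))
    sd[stats$degenerate] <- epsilon
  }
  sweep(sweep(M, 2, stats$mean), 2, sd, "/")
}

#' Apply frozen normalization statistics to a connectogram
#'
#' Maps every cell value to \code{(value - mean) / sd}, using statistics
#' fitted on the training cohort; the same frozen statistics are applied to
#' training, testing and patient subjects alike.
#'
#' @param cg A \code{\link{connectogram}}.
#' @param stats A \code{"norm_stats"} object from
#'   \code{\link{fit_step_normalization}}.
#' @param epsilon Optional positive SD substitute for degenerate cells.
#' @return A normalized \code{\link{connectogram}}.
#' @export
apply_normalization <- function(cg, stats, epsilon = NULL) {
  stopifnot(inherits(cg, "connectogram"), inherits(stats, "norm_stats"))
  M <- .apply_norm_matrix(matrix(.cg_to_row(cg), nrow = 1), stats, epsilon)
  .row_to_cg(M[1, ], attr(cg, "subject_id"))
}

#' Invert a normalization (for round-trip checks)
#' @inheritParams apply_normalization
#' @export
invert_normalization <- function(cg, stats, epsilon = NULL) {
  stopifnot(inherits(cg, "connectogram"), inherits(stats, "norm_stats"))
  sd <- stats$sd
  if (any(stats$degenerate)) {
    if (is.null(epsilon)) stop("degenerate cell without epsilon substitution")
    sd[stats$degenerate] <- epsilon
  }
  row <- .cg_to_row(cg) * sd + stats$mean
  .row_to_cg(row, attr(cg, "subject_id"))
}

#' Age-association step weights
#'
#' For every (tract, step, index) cell, fits ordinary least squares of the
#' (smoothed, normalized) value on age and age squared, takes the p-value of
#' the model-vs-intercept F test (2 and n - 3 degrees of freedom), and uses
#' \code{-log10(max(p, pvalue_floor))} as the step's raw weight.  Raw weights
#' are then renormalized within each (tract, index) profile to sum 1 when
#' \code{normalize_weights} is set, so downstream reduction is a weighted
#' mean.
#'
#' @param normalized_training List of normalized \code{\link{connectogram}}s
#'   (or a flat matrix), >= 4 subjects.
#' @param ages Numeric vector of chronological ages (non-constant).
#' @param params A \code{\link{preprocess_params}}.
#' @return An object of class \code{"step_weights"}: \code{w} (532 x 100
#'   weight matrix, rows in canonical feature order), with the per-cell-step
#'   p-values and F statistics attached as \code{p} and \code{F}.
#' @export
compute_age_weights <- function(normalized_training, ages,
                                params = preprocess_params()) {
  M <- if (is.matrix(normalized_training)) normalized_training else
    .cg_list_to_matrix(normalized_training)
  n <- nrow(M)
  if (n < 4L) stop("need at least 4 subjects to fit the age GLM")
  if (length(ages) != n) stop("ages must match the number of subjects")
  if (stats::sd(ages) == 0) stop("singular design: ages are constant")

  X <- cbind(1, ages, ages^2)
  qrX <- qr(X)
  if (qrX$rank < 3L) stop("singular design in the age GLM")
  resid <- qr.resid(qrX, M)
  rss <- colSums(resid^2)
  tss <- colSums(sweep(M, 2, colMeans(M))^2)
  df2 <- n - 3L
  Fs <- pmax(0, ((tss - rss) / 2) / (rss / df2))
  Fs[tss == 0] <- 0
  p <- stats::pf(Fs, 2, df2, lower.tail = FALSE)
  p[tss == 0] <- 1
  w_raw <- -log10(pmax(p, params$pvalue_floor))

  W <- matrix(w_raw, nrow = .TA$n_cells, ncol = .TA$n_steps, byrow = TRUE,
              dimnames = list(.TA$features, NULL))
  if (params$normalize_weights) {
    s <- rowSums(W)
    ok <- s > 0
    W[ok, ] <- W[ok, ] / s[ok]
  }
  structure(list(w = W,
                 p = matrix(p, .TA$n_cells, .TA$n_steps, byrow = TRUE,
                            dimnames = list(.TA$features, NULL)),
                 F = matrix(Fs, .TA$n_cells, .TA$n_steps, byrow = TRUE,
                            dimnames = list(.TA$features, NULL)),
                 normalized = params$normalize_weights, n = n),
            class = "step_weights")
}

# flat reduction: n x 53200 matrix -> n x 532 feature matrix
.reduce_matrix <- function(M, weights) {
  W <- weights$w
  s <- rowSums(W)
  if (any(s == 0))
    stop("all-zero weight vector for cell(s): ",
         paste(utils::head(rownames(W)[s == 0], 5), collapse = ", "))
  wflat <- as.vector(t(W / s))                 # cell-major, step fastest
  Mw <- sweep(M, 2, wflat, "*")
  A <- matrix(t(Mw), nrow = .TA$n_steps)       # steps x (cells * n)
  Fm <- matrix(colSums(A), nrow = nrow(M), byrow = TRUE,
               dimnames = list(rownames(M), .TA$features))
  Fm
}

#' Reduce a connectogram to 532 tract features
#'
#' Computes, for every (tract, index) cell, the weighted average of its 100
#' steps under the fitted age-association weights, yielding a named
#' length-532 feature vector in canonical order.
#'
#' @param cg A \code{\link{connectogram}} (already smoothed and normalized).
#' @param weights A \code{"step_weights"} object.
#' @return Named numeric vector of length 532.
#' @export
reduce_to_features <- function(cg, weights) {
  stopifnot(inherits(cg, "connectogram"), inherits(weights, "step_weights"))
  .reduce_matrix(matrix(.cg_to_row(cg), nrow = 1,
                        dimnames = list(attr(cg, "subject_id"), NULL)),
                 weights)[1, ]
}

#' Fit the full feature pipeline on a training cohort
#'
#' Convenience wrapper that smooths the training connectograms, fits the
#' per-step normalization on the smoothed data, and fits the age-association
#' weights on the normalized data.  All statistics are frozen: applying the
#' pipeline to any other cohort reuses the training statistics and weights.
#'
#' @param training List of training \code{\link{connectogram}}s.
#' @param ages Training ages.
#' @param params A \code{\link{preprocess_params}}.
#' @param epsilon Optional degenerate-cell SD substitute.
#' @return An object of class \code{"feature_pipeline"}.
#' @export
fit_feature_pipeline <- function(training, ages,
                                 params = preprocess_params(),
                                 epsilon = NULL) {
  M <- if (is.matrix(training)) training else .cg_list_to_matrix(training)
  S <- .smoothing_matrix(params$smooth_sigma, params$kernel_truncation,
                         params$boundary_mode)
  Ms <- .smooth_matrix_rows(M, S)
  stats <- fit_step_normalization(Ms)
  Mn <- .apply_norm_matrix(Ms, stats, epsilon)
  weights <- compute_age_weights(Mn, ages, params)
  structure(list(params = params, S = S, stats = stats, weights = weights,
                 epsilon = epsilon),
            class = "feature_pipeline")
}

#' Apply a fitted feature pipeline to a cohort
#'
#' @param conns List of \code{\link{connectogram}}s (or a flat value matrix).
#' @param pipeline A \code{"feature_pipeline"}.
#' @return Numeric matrix, subjects x 532 named features.
#' @export
pipeline_features <- function(conns, pipeline) {
  stopifnot(inherits(pipeline, "feature_pipeline"))
  M <- if (is.matrix(conns)) conns else .cg_list_to_matrix(conns)
  Ms <- .smooth_matrix_rows(M, pipeline$S)
  Mn <- .apply_norm_matrix(Ms, pipeline$stats, pipeline$epsilon)
  .reduce_matrix(Mn, pipeline$weights)
}

#' Simulate tract features directly, in chunks
#'
#' Draws a healthy cohort from the generator and immediately reduces it to
#' 532-dimensional features through a fitted pipeline, without keeping the
#' full connectograms in memory.  Intended for large calibration simulations
#' (thousands of subjects).  The draw is deterministic given \code{config}
#' and \code{chunk_size}.
#'
#' @param config A \code{\link{generator_config}}.
#' @param pipeline A fitted \code{"feature_pipeline"}.
#' @param ages,sexes Optional demographic overrides.
#' @param chunk_size Subjects per generation chunk.
#' @return List with \code{features} (n x 532 matrix) and \code{cohort}
#'   (data frame).
#' @export
simulate_feature_cohort <- function(config, pipeline, ages = NULL,
                                    sexes = NULL, chunk_size = 250L) {
  stopifnot(inherits(config, "generator_config"),
            inherits(pipeline, "feature_pipeline"))
  n <- config$n_subjects
  out <- matrix(NA_real_, n, .TA$n_cells,
                dimnames = list(NULL, .TA$features))
  cohort <- NULL
  withr::with_seed(config$seed, {
    cohort <- .gen_demographics(config, ages, sexes, group = "healthy")
    starts <- seq(1L, n, by = chunk_size)
    for (s0 in starts) {
      idx <- s0:min(n, s0 + chunk_size - 1L)
      sub_cfg <- config
      sub_cfg$n_subjects <- length(idx)
      M <- .gen_value_matrix(sub_cfg, cohort$age[idx],
                             cohort$sex[idx] == "M")
      Ms <- .smooth_matrix_rows(M, pipeline$S)
      Mn <- .apply_norm_matrix(Ms, pipeline$stats, pipeline$epsilon)
      out[idx, ] <- .reduce_matrix(Mn, pipeline$weights)
    }
  })
  rownames(out) <- cohort$subject_id
  list(features = out, cohort = cohort)
}
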