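#' ANCOVA on PAD scores across groups
#'
#' Linear-model analysis of covariance testing the group factor on PAD while
#' adjusting for age, sex and handedness: the F statistic compares the full
#' model \code{pad ~ group + covariates} against the covariates-only model,
#' with \code{(g - 1, n - g - c)} degrees of freedom for g groups and c
#' covariates.
#'
#' @param pads Numeric PAD scores.
#' @param groups Group factor (>= 3 levels represented).
#' @param age,sex,handedness Covariates (complete).
#' @return List with \code{F}, \code{p}, \code{df} (length 2).
#' @export
ancova_pad <- function(pads, groups, age, sex, handedness) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 3L)
    stop("need at least 3 groups represented")
  covars <- data.frame(age = age, sex = .encode_sex(sex),
                       handedness = handedness)
  if (anyNA(covars) || anyNA(pads)) stop("covariates and PAD must be complete")
  full <- stats::lm(pads ~ groups + age + sex + handedness, data = covars)
  if (full$rank < nlevels(droplevels(groups)) + 3L)
    stop("rank-deficient design")
  red <- stats::lm(pads ~ age + sex + handedness, data = covars)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  df1 <- nlevels(droplevels(groups)) - 1L
  df2 <- length(pads) - nlevels(droplevels(groups)) - ncol(covars)
  Fv <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  if (!is.finite(Fv)) Fv <- 0   # no residual variance and no group effect
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Pairwise post hoc t tests on PAD with Bonferroni correction
#'
#' Two-sample t tests for every pair of groups (Welch by default, pooled
#' optionally); raw p-values are multiplied by the number of pairs and
#' capped at 1.
#'
#' @param pads Numeric PAD scores.
#' @param groups Group factor.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Data frame with one row per pair: \code{group1}, \code{group2},
#'   \code{t}, \code{df}, \code{p_raw}, \code{p_bonferroni}.
#' @export
posthoc_pairwise <- function(pads, groups, var_equal = FALSE) {
  groups <- droplevels(factor(groups))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(j) {
    a <- pads[groups == pairs[1, j]]
    b <- pads[groups == pairs[2, j]]
    if (length(a) < 2L || length(b) < 2L)
      stop("each group needs at least 2 subjects")
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mass-univariate testing of deviation z-scores
#'
#' One-sample t test of the patients' z-scores against 0 in each of the 532
#' (tract, index) cells, with multiple-comparison adjustment across cells
#' (Benjamini-Hochberg by default, Bonferroni optionally) and the
#' one-sample standardized effect size \code{d = mean(z) / sd(z)}.
#' Cells with zero within-group SD are flagged and excluded from testing.
#'
#' @param zgrids Patients x 532 matrix of z-scores.
#' @param adjust \code{"BH"} or \code{"bonferroni"}.
#' @param alpha Significance level on the adjusted p-values.
#' @return Data frame with one row per cell: \code{feature}, \code{tract},
#'   \code{index}, \code{t}, \code{p}, \code{p_adjusted}, \code{d},
#'   \code{significant}, \code{degenerate}.
#' @export
mass_univariate_z <- function(zgrids, adjust = c("BH", "bonferroni"),
                              alpha = 0.05) {
  adjust <- match.arg(adjust)
  Z <- as.matrix(zgrids)
  n <- nrow(Z)
  if (n < 2L) stop("need at least 2 patients")
  m <- colMeans(Z)
  s <- apply(Z, 2, stats::sd)
  # a cell that is exactly zero in every patient shows no deviation (t = 0);
  # a nonzero-constant cell has an undefined t and is flagged instead
  degenerate <- s == 0 & m != 0
  tv <- ifelse(degenerate, NA_real_, ifelse(s == 0, 0, m / (s / sqrt(n))))
  p <- 2 * stats::pt(-abs(tv), df = n - 1)
  p_adj <- rep(NA_real_, length(p))
  ok <- !degenerate
  p_adj[ok] <- stats::p.adjust(p[ok], method = adjust)
  d <- ifelse(degenerate, NA_real_, ifelse(s == 0, 0, m / s))
  feat <- colnames(Z) %||% .TA$features
  data.frame(feature = feat,
             tract = sub("\\.[^.]+$", "", feat),
             index = sub("^.*\\.", "", feat),
             t = tv, p = p, p_adjusted = p_adj, d = d,
             significant = !is.na(p_adj) & p_adj <= alpha,
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the top fraction of cells by absolute effect size
#'
#' Ranks all cells by |d| descending (ties broken by canonical feature
#' order) and selects the top \code{ceiling(fraction * n_cells)}; with the
#' default 5\% over the 532-cell grid this is exactly 27 features.
#'
#' @param grid Output of \code{\link{mass_univariate_z}}.
#' @param fraction Fraction in (0, 1].
#' @param significant_only Restrict the ranking to significant cells first.
#' @return Character vector of selected feature names.
#' @export
select_top_features <- function(grid, fraction = 0.05,
                                significant_only = FALSE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  pool <- grid
  if (significant_only) pool <- pool[pool$significant %in% TRUE, ]
  n_sel <- ceiling(fraction * nrow(grid))
  pool <- pool[!is.na(pool$d), ]
  ord <- order(-abs(pool$d), match(pool$feature, .TA$features))
  utils::head(pool$feature[ord], n_sel)
}

#' PCA attribution of PAD to selected deviation features
#'
#' Principal component analysis (column-centered, unscaled) of the patients
#' x selected-features z-score matrix.  The first component is taken as the
#' representative deviation axis, its sign oriented so that the slope of the
#' PAD regression is positive, and PAD is regressed on the PC1 scores by
#' simple linear regression.  The contribution of feature j is
#' \code{100 * loading_j^2} (loadings have unit norm, so contributions sum
#' to 100); tract and index contributions are sums over the selected
#' features of that tract or index.  Absolute-loading normalization is
#' available as an option.
#'
#' @param z Patients x selected-features z matrix (>= 3 patients).
#' @param pads PAD scores, same subjects.
#' @param contribution \code{"squared"} (default) or \code{"absolute"}.
#' @return List with \code{selected_features}, \code{pc1_scores},
#'   \code{pc1_loadings}, \code{variance_explained_pc1} (percent),
#'   \code{feature_contributions}, \code{tract_contributions},
#'   \code{index_contributions} (percent, each summing to 100), and
#'   \code{regression} (F, p, r_squared, slope).
#' @export
pca_attribution <- function(z, pads, contribution = c("squared", "absolute")) {
  contribution <- match.arg(contribution)
  Z <- as.matrix(z)
  if (nrow(Z) < 3L) stop("need at least 3 patients")
  if (ncol(Z) < 1L) stop("need at least 1 selected feature")
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  fit <- stats::lm(pads ~ scores)
  if (!is.na(stats::coef(fit)[2]) && stats::coef(fit)[2] < 0) {
    scores <- -scores; loadings <- -loadings
    fit <- stats::lm(pads ~ scores)
  }
  sm <- summary(fit)
  contrib <- if (contribution == "squared") loadings^2 else abs(loadings)
  contrib <- 100 * contrib / sum(contrib)
  feat <- colnames(Z)
  tracts <- sub("\\.[^.]+$", "", feat)
  idx <- sub("^.*\\.", "", feat)
  by_group <- function(g) {
    s <- sort(tapply(contrib, g, sum), decreasing = TRUE)
    stats::setNames(as.numeric(s), names(s))
  }
  Fv <- unname(sm$fstatistic[1])
  list(selected_features = feat,
       pc1_scores = scores,
       pc1_loadings = loadings,
       variance_explained_pc1 = 100 * pc$sdev[1]^2 / sum(pc$sdev^2),
       feature_contributions = stats::setNames(contrib, feat),
       tract_contributions = by_group(tracts),
       index_contributions = by_group(idx),
       regression = list(F = Fv,
                         p = stats::pf(Fv, sm$fstatistic[2], sm$fstatistic[3],
                                       lower.tail = FALSE),
                         r_squared = sm$r.squared,
                         slope = unname(stats::coef(fit)[2])))
}

# residualize a vector on a confounder data frame (intercept always included)
.residualize <- function(y, confounders) {
  if (is.null(confounders) || ncol(as.data.frame(confounders)) == 0L)
    return(y - mean(y))
  X <- stats::model.matrix(~ ., data = as.data.frame(confounders))
  stats::lm.fit(X, y)$residuals
}

# confound-adjusted correlation on residuals; p from a t approximation with
# partial-correlation degrees of freedom n - 2 - k
.partial_cor <- function(pad, var, confounders, method) {
  rp <- .residualize(pad, confounders)
  rv <- .residualize(var, confounders)
  if (method == "spearman") { rp <- rank(rp); rv <- rank(rv) }
  r <- stats::cor(rp, rv)
  k <- if (is.null(confounders)) 0L else ncol(as.data.frame(confounders))
  df <- length(pad) - 2L - k
  tv <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tv), df), df = df)
}

#' Confound-adjusted correlations of PAD with clinical variables
#'
#' For each clinical variable (age of onset, duration of illness, seizure
#' frequency), both PAD and the variable are residualized on the confounders
#' (age, sex, number of anti-epileptic drug classes) by ordinary least
#' squares.  If both residual vectors pass a Shapiro-Wilk normality test at
#' \code{normality_alpha}, the Pearson correlation of the residuals is
#' reported; otherwise the Spearman correlation (ranks of residuals).
#' Optionally, observations whose clinical value lies more than
#' \code{outlier_sd} SDs from the variable mean are excluded first.
#'
#' @param pads PAD scores.
#' @param cohort Patient table with clinical fields and confounders.
#' @param variables Clinical variable names.
#' @param confounders Confounder column names (regressed out).
#' @param normality_alpha Shapiro-Wilk level gating Pearson vs Spearman.
#' @param outlier_sd Exclusion threshold in SD units (Inf disables).
#' @return Data frame with one row per variable: \code{variable},
#'   \code{method}, \code{r}, \code{p}, \code{n}, \code{n_excluded}.
#' @export
clinical_correlations <- function(pads, cohort,
                                  variables = c("age_of_onset",
                                                "duration_of_illness",
                                                "seizure_frequency"),
                                  confounders = c("age", "sex",
                                                  "n_aed_classes"),
                                  normality_alpha = 0.05,
                                  outlier_sd = Inf) {
  stopifnot(length(pads) == nrow(cohort))
  if (length(pads) < 5L) stop("need at least 5 patients")
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("unknown clinical variable: ", v)
    keep <- !is.na(x) & !is.na(pads)
    if (is.finite(outlier_sd)) {
      zx <- abs(x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
      keep <- keep & zx <= outlier_sd
    }
    x <- x[keep]; p <- pads[keep]
    if (stats::sd(x) == 0)
      stop("undefined correlation: '", v, "' is constant")
    conf <- if (length(confounders))
      data.frame(lapply(cohort[keep, confounders, drop = FALSE],
                        function(col) if (is.character(col))
                          .encode_sex(col) else col))
    else NULL
    rp <- .residualize(p, conf)
    rv <- .residualize(x, conf)
    normal <- stats::shapiro.test(rp)$p.value > normality_alpha &&
      stats::shapiro.test(rv)$p.value > normality_alpha
    method <- if (normal) "pearson" else "spearman"
    pc <- .partial_cor(p, x, conf, method)
    data.frame(variable = v, method = method, r = pc$r, p = pc$p,
               n = length(x), n_excluded = sum(!keep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bootstrap confidence interval for a confound-adjusted correlation
#'
#' Resamples subjects with replacement, recomputes the residualized
#' correlation per replicate (with the correlation method fixed to the one
#' chosen on the original sample), and reports the percentile 95\% CI.
#' Replicates in which either variable or any confounder is degenerate are
#' skipped and counted; a warning is attached when more than 10\% are
#' skipped.
#'
#' @param pads,clinical Numeric vectors.
#' @param confounders Data frame of confounders (or NULL).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param method \code{"pearson"}, \code{"spearman"}, or \code{"auto"}
#'   (normality-gated on the original sample).
#' @param normality_alpha Gate level for \code{method = "auto"}.
#' @return List with \code{r} (original-sample estimate), \code{ci_lower},
#'   \code{ci_upper}, \code{n_boot}, \code{n_skipped}, \code{method},
#'   \code{seed}, \code{warning}.
#' @export
bootstrap_correlation <- function(pads, clinical, confounders = NULL,
                                  n_boot = 2000L, seed = 1L,
                                  method = "auto", normality_alpha = 0.05) {
  n <- length(pads)
  if (n < 5L) stop("need at least 5 subjects")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  conf <- if (!is.null(confounders)) as.data.frame(confounders) else NULL
  if (method == "auto") {
    rp <- .residualize(pads, conf); rv <- .residualize(clinical, conf)
    method <- if (stats::shapiro.test(rp)$p.value > normality_alpha &&
                  stats::shapiro.test(rv)$p.value > normality_alpha)
      "pearson" else "spearman"
  }
  r_hat <- .partial_cor(pads, clinical, conf, method)$r
  rs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cb <- if (!is.null(conf)) conf[idx, , drop = FALSE] else NULL
      if (stats::sd(clinical[idx]) == 0 || stats::sd(pads[idx]) == 0)
        return(NA_real_)
      if (!is.null(cb)) {
        num <- vapply(cb, function(col)
          stats::var(as.numeric(as.factor(col))), numeric(1))
        if (any(num == 0)) cb <- cb[, num > 0, drop = FALSE]
      }
      r <- .partial_cor(pads[idx], clinical[idx], cb, method)$r
      if (is.na(r)) NA_real_ else r
    }, numeric(1))
  })
  skipped <- sum(is.na(rs))
  rs <- rs[!is.na(rs)]
  ci <- unname(stats::quantile(rs, c(0.025, 0.975), type = 7))
  warn <- if (skipped > 0.1 * n_boot)
    sprintf("%d of %d bootstrap replicates skipped (degenerate resample)",
            skipped, n_boot) else NULL
  list(r = r_hat, ci_lower = ci[1], ci_upper = ci[2],
       n_boot = n_boot, n_skipped = skipped, method = method,
       seed = seed, warning = warn)
}
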