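test_that("ANCOVA group F is zero when groups are interchangeable", {
  pads <- rep(c(2, 5, 1, 7, 4, 8, 3, 6), 3)
  groups <- rep(c("a", "b", "c"), each = 8)
  age <- rep(seq(30, 44, by = 2), 3)
  sex <- rep(rep(c("M", "F"), 4), 3)
  hand <- rep(c(70, 85, 60, 90, 75, 95, 65, 80), 3)
  res <- ancova_pad(pads, groups, age, sex, hand)
  expect_equal(res$F, 0, tolerance = 1e-10)
  expect_identical(res$df, c(2L, 24L - 3L - 3L))
})

test_that("ANCOVA matches an explicit design-matrix oracle", {
  set.seed(71)
  n <- 30
  groups <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(.4, .3, .3))
  age <- runif(n, 20, 60); sex <- sample(c("M", "F"), n, TRUE)
  hand <- runif(n, -100, 100)
  pads <- 2 * (groups == "b") + 0.1 * age + rnorm(n)
  res <- ancova_pad(pads, groups, age, sex, hand)
  # brute force: residual sums of squares via explicit projections
  Xf <- cbind(1, groups == "b", groups == "c", age, sex == "M", hand)
  Xr <- cbind(1, age, sex == "M", hand)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% pads)
    sum((pads - X %*% b)^2)
  }
  F_oracle <- ((rss(Xr) - rss(Xf)) / 2) / (rss(Xf) / (n - 6))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(F_oracle, 2, n - 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANCOVA detects a 10-year PAD shift in a group of 17 with high power", {
  hits <- 0L
  for (r in 1:100) {
    pads <- withr::with_seed(700 + r, {
      c(rnorm(37, 0, 6), rnorm(18, 0, 6), rnorm(17, 10, 6))
    })
    groups <- rep(c("controls", "lmtle", "rmtle"), c(37, 18, 17))
    age <- withr::with_seed(800 + r, runif(72, 25, 55))
    sex <- withr::with_seed(900 + r, sample(c("M", "F"), 72, TRUE))
    hand <- withr::with_seed(1000 + r, runif(72, 40, 100))
    if (ancova_pad(pads, groups, age, sex, hand)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("post hoc pairwise tests follow Welch and Bonferroni arithmetic", {
  a <- c(1, 2, 3, 4, 5)
  res <- posthoc_pairwise(rep(a, 3), rep(c("x", "y", "z"), each = 5))
  expect_true(all(res$t == 0))
  expect_true(all(res$p_bonferroni == 1))
  expect_identical(nrow(res), 3L)
  # Bonferroni multiplies by the number of pairs
  expect_equal(min(1, 0.02 * 3), 0.06)
  # Welch degrees of freedom on a 5-vs-5 toy match the closed form
  x <- c(1.2, 0.8, 1.9, 2.4, 1.1); y <- c(3.1, 5.2, 4.4, 2.8, 6.0)
  res2 <- posthoc_pairwise(c(x, y), rep(c("x", "y"), each = 5))
  vx <- var(x) / 5; vy <- var(y) / 5
  df_ws <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 4)
  expect_equal(res2$df, df_ws, tolerance = 1e-10)
  expect_equal(res2$t, (mean(x) - mean(y)) / sqrt(vx + vy),
               tolerance = 1e-10)
  expect_error(posthoc_pairwise(c(1, 2, 3), c("x", "x", "y")), "at least 2")
})

test_that("mass-univariate testing handles null, shifted and degenerate cells", {
  set.seed(72)
  Z <- matrix(rnorm(20 * 532), 20, 532, dimnames = list(NULL, feature_names()))
  Z[, 1] <- 0                 # exactly zero deviation
  Z[, 2] <- 2                 # nonzero constant: undefined t
  Z[, 3] <- Z[, 3] + 3        # strong real shift
  res <- mass_univariate_z(Z)
  expect_equal(res$t[1], 0)
  expect_false(res$significant[1])
  expect_true(res$degenerate[2])
  expect_true(is.na(res$d[2]))
  expect_true(res$significant[3])
  expect_equal(res$d[3], mean(Z[, 3]) / sd(Z[, 3]), tolerance = 1e-12)
  # Bonferroni option is more conservative than BH
  bh <- mass_univariate_z(Z, adjust = "BH")
  bf <- mass_univariate_z(Z, adjust = "bonferroni")
  expect_true(all(bf$p_adjusted >= bh$p_adjusted - 1e-12, na.rm = TRUE))
})

test_that("top-effect-size selection obeys the ceiling rule and tie-breaks", {
  set.seed(73)
  Z <- matrix(rnorm(15 * 532), 15, 532, dimnames = list(NULL, feature_names()))
  grid <- mass_univariate_z(Z)
  expect_length(select_top_features(grid, 0.05), 27)   # ceil(0.05 * 532)
  grid100 <- grid[1:100, ]
  expect_length(select_top_features(grid100, 0.05), 5) # ceil(0.05 * 100)
  expect_error(select_top_features(grid, 0), "fraction")
  # exact ties resolved by canonical feature order
  tied <- grid
  tied$d <- rep(1, 532)
  sel <- select_top_features(tied, 0.05)
  expect_identical(sel, feature_names()[1:27])
})

test_that("PCA attribution matches a brute-force eigendecomposition", {
  set.seed(74)
  Z <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(NULL, feature_names()[c(1, 9, 17, 25)]))
  pads <- rnorm(6)
  att <- pca_attribution(Z, pads)
  eig <- eigen(cov(Z))
  expect_equal(abs(att$pc1_loadings), abs(eig$vectors[, 1]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(att$variance_explained_pc1,
               100 * eig$values[1] / sum(eig$values), tolerance = 1e-10)
  expect_equal(sum(att$pc1_loadings^2), 1, tolerance = 1e-12)
  expect_equal(sum(att$feature_contributions), 100, tolerance = 1e-9)
  expect_equal(sum(att$tract_contributions), 100, tolerance = 0.1)
  expect_equal(sum(att$index_contributions), 100, tolerance = 0.1)
  # orientation: the PAD regression slope is non-negative
  expect_gte(att$regression$slope, 0)
})

test_that("PCA attribution degenerate and exact cases behave as defined", {
  set.seed(75)
  # one selected feature: that tract owns 100% of the contribution
  z1 <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "UF_R.RD"))
  att1 <- pca_attribution(z1, rnorm(8))
  expect_equal(unname(att1$tract_contributions["UF_R"]), 100)
  # two features with equal |loading| on different tracts: 50% / 50%
  base <- rnorm(10)
  z2 <- cbind(base, -base) + 0
  colnames(z2) <- c("UF_R.RD", "ILF_L.MD")
  att2 <- pca_attribution(z2, rnorm(10))
  expect_equal(unname(att2$tract_contributions), c(50, 50), tolerance = 1e-9)
  # PAD an exact linear function of PC1 gives R^2 = 1
  z3 <- matrix(rnorm(9 * 3), 9, 3,
               dimnames = list(NULL, feature_names()[1:3]))
  att3 <- suppressWarnings(pca_attribution(z3, 2 + 0.5 * prcomp(z3)$x[, 1]))
  expect_equal(att3$regression$r_squared, 1, tolerance = 1e-10)
  expect_error(pca_attribution(z3[1:2, ], c(1, 2)), "at least 3")
})

test_that("confound-adjusted correlations reduce to plain correlations without confounders", {
  set.seed(76)
  n <- 40
  pad <- rnorm(n); onset <- rnorm(n, 14, 5)
  cohort <- data.frame(age_of_onset = onset, duration_of_illness = rnorm(n),
                       seizure_frequency = rgamma(n, 2, 1))
  cc <- clinical_correlations(pad, cohort, confounders = character(0))
  ct <- cor.test(pad, onset)
  row <- cc[cc$variable == "age_of_onset", ]
  if (row$method == "pearson") {
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("residualization removes variance shared with a confounder", {
  set.seed(77)
  n <- 200
  age <- runif(n, 20, 60)
  pad <- 0.3 * age + rnorm(n)
  # clinical variable driven almost entirely by the age confounder
  cohort <- data.frame(age_of_onset = 2 * age + 5 + rnorm(n),
                       duration_of_illness = rnorm(n),
                       seizure_frequency = rgamma(n, 2, 1),
                       age = age, sex = sample(c("M", "F"), n, TRUE),
                       n_aed_classes = sample(1:4, n, TRUE))
  raw_r <- cor(pad, cohort$age_of_onset)
  expect_gt(abs(raw_r), 0.5)                  # strongly confounded raw r
  cc <- clinical_correlations(pad, cohort)
  # adjusted correlation collapses to sampling noise (~3 SE at n = 200)
  expect_lt(abs(cc$r[cc$variable == "age_of_onset"]), 0.2)
  expect_error(
    clinical_correlations(pad, transform(cohort, age_of_onset = 1),
                          confounders = character(0)),
    "constant")
})

test_that("the Spearman branch is invariant under monotone transforms", {
  set.seed(78)
  n <- 30
  pad <- rexp(n)                              # skewed: fails normality
  x <- rexp(n, 0.3)
  cohort1 <- data.frame(seizure_frequency = x)
  cohort2 <- data.frame(seizure_frequency = exp(x / 2))
  c1 <- clinical_correlations(pad, cohort1, variables = "seizure_frequency",
                              confounders = character(0))
  c2 <- clinical_correlations(pad, cohort2, variables = "seizure_frequency",
                              confounders = character(0))
  expect_identical(c1$method, "spearman")
  expect_equal(c1$r, c2$r, tolerance = 1e-12)
})

test_that("partial correlation matches an explicit residual oracle", {
  set.seed(79)
  n <- 25
  conf <- data.frame(age = runif(n, 20, 60),
                     aed = sample(1:4, n, TRUE))
  pad <- 0.2 * conf$age + rnorm(n)
  x <- -0.1 * conf$age + rnorm(n)
  got <- tractage:::.partial_cor(pad, x, conf, "pearson")
  X <- cbind(1, conf$age, conf$aed)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  r_oracle <- cor(pad - H %*% pad, x - H %*% x)
  expect_equal(got$r, as.vector(r_oracle), tolerance = 1e-10)
})

test_that("bootstrap CIs are seeded, stable and collapse for collinear data", {
  x <- seq(1, 20)
  ci <- bootstrap_correlation(x, 2 * x + 3, n_boot = 200, seed = 5)
  expect_equal(ci$ci_lower, 1)
  expect_equal(ci$ci_upper, 1)
  set.seed(80)
  pad <- rnorm(30); clin <- 0.6 * pad + rnorm(30, sd = 0.8)
  a <- bootstrap_correlation(pad, clin, n_boot = 500, seed = 9,
                             method = "pearson")
  b <- bootstrap_correlation(pad, clin, n_boot = 500, seed = 9,
                             method = "pearson")
  expect_identical(a$ci_lower, b$ci_lower)
  # Monte-Carlo stability across seeds at large n_boot
  c1 <- bootstrap_correlation(pad, clin, n_boot = 10000, seed = 1,
                              method = "pearson")
  c2 <- bootstrap_correlation(pad, clin, n_boot = 10000, seed = 2,
                              method = "pearson")
  expect_lt(abs(c1$ci_lower - c2$ci_lower), 0.02)
  expect_lt(abs(c1$ci_upper - c2$ci_upper), 0.02)
})
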