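test_that("smoothing with sigma 0 is the identity and constants are preserved", {
  cg <- ta_flat_connectogram(3.7)
  p0 <- preprocess_params(smooth_sigma = 0)
  expect_identical(unclass(smooth_profiles(cg, p0))[, , ],
                   unclass(cg)[, , ])
  sm <- smooth_profiles(cg, preprocess_params(smooth_sigma = 2))
  expect_equal(as.vector(unclass(sm)), rep(3.7, 76 * 100 * 7))
  expect_error(preprocess_params(smooth_sigma = -1), "smooth_sigma")
})

test_that("smoothing matches a brute-force discrete convolution oracle", {
  # oracle: explicit double loop over kernel taps with reflected indices
  brute_smooth <- function(x, sigma, trunc = 3) {
    n <- length(x)
    r <- max(1, ceiling(trunc * sigma))
    g <- exp(-(-r:r)^2 / (2 * sigma^2)); g <- g / sum(g)
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (m in seq_along(g)) {
        idx <- i + (m - r - 1)
        while (idx < 1 || idx > n) {
          if (idx < 1) idx <- 1 - idx
          if (idx > n) idx <- 2 * n + 1 - idx
        }
        acc <- acc + g[m] * x[idx]
      }
      out[i] <- acc
    }
    out
  }
  vals <- array(0, c(76, 100, 7))
  vals[3, 51, 2] <- 1                         # unit impulse at step 50
  cg <- connectogram(vals, "imp")
  sm <- smooth_profiles(cg, preprocess_params(smooth_sigma = 2))
  expect_equal(unname(unclass(sm)[3, , 2]),
               brute_smooth(vals[3, , 2], 2), tolerance = 1e-12)
  # and on a random profile near the boundary
  set.seed(4)
  vals[3, , 2] <- rnorm(100)
  cg2 <- connectogram(vals, "rnd")
  sm2 <- smooth_profiles(cg2, preprocess_params(smooth_sigma = 3.5))
  expect_equal(unname(unclass(sm2)[3, , 2]),
               brute_smooth(vals[3, , 2], 3.5), tolerance = 1e-12)
})

test_that("per-step normalization has the textbook sample moments", {
  mk <- function(v) connectogram(array(v, c(76, 100, 7)), paste0("s", v))
  stats <- fit_step_normalization(list(mk(1), mk(2), mk(3)))
  expect_equal(unname(stats$mean[1]), 2)
  expect_equal(unname(stats$sd[1]), 1)        # sample SD of {1,2,3}
  expect_false(any(stats$degenerate))

  same <- fit_step_normalization(list(mk(2), mk(2)))
  expect_true(all(same$degenerate))
  expect_error(apply_normalization(mk(2), same), "degenerate cell")
  eps_ok <- apply_normalization(mk(2), same, epsilon = 1)
  expect_equal(as.vector(unclass(eps_ok)), rep(0, 76 * 100 * 7))
})

test_that("normalizing the training set itself gives mean 0 and SD 1", {
  cfg <- generator_config(n_subjects = 8, seed = 41)
  conns <- generate_cohort(cfg)$connectograms
  stats <- fit_step_normalization(conns)
  normed <- lapply(conns, apply_normalization, stats = stats)
  M <- tractage:::.cg_list_to_matrix(normed)
  expect_lt(max(abs(colMeans(M))), 1e-9)
  expect_lt(max(abs(apply(M, 2, sd) - 1)), 1e-9)
})

test_that("normalization is a frozen affine map that inverts exactly", {
  cfg_a <- generator_config(n_subjects = 5, seed = 42)
  cfg_b <- generator_config(n_subjects = 3, seed = 43)
  stats <- fit_step_normalization(generate_cohort(cfg_a)$connectograms)
  b <- generate_cohort(cfg_b)$connectograms[[2]]
  z <- apply_normalization(b, stats)
  back <- invert_normalization(z, stats)
  expect_equal(unclass(back)[, , ], unclass(b)[, , ], tolerance = 1e-12)
  # value at the training mean maps to 0; mean + sd maps to 1
  v0 <- tractage:::.row_to_cg(stats$mean, "at-mean")
  expect_equal(as.vector(unclass(apply_normalization(v0, stats))),
               rep(0, 53200))
  v1 <- tractage:::.row_to_cg(stats$mean + stats$sd, "at-sd")
  expect_equal(as.vector(unclass(apply_normalization(v1, stats))),
               rep(1, 53200))
})

test_that("age weights follow the -log10 p definition with a floor", {
  # deterministic profile: exact quadratic in age -> p underflows the floor
  n <- 40
  ages <- seq(20, 80, length.out = n)
  M <- matrix(withr::with_seed(5, rnorm(n * 53200, sd = 1)), n, 53200)
  M[, 1] <- 0.1 * ages                        # noiseless linear cell-step
  pp <- preprocess_params(normalize_weights = FALSE)
  w <- compute_age_weights(M, ages, pp)
  expect_equal(unname(w$w[1, 1]), 300)        # -log10 of the 1e-300 floor
  # -log10 arithmetic on the computed p-values
  expect_equal(w$w[2, ], -log10(w$p[2, ]), tolerance = 1e-12)
  expect_true(all(w$w >= 0 & is.finite(w$w)))
  # normalized weights sum to one per (tract, index) profile
  wn <- compute_age_weights(M, ages, preprocess_params())
  expect_lt(max(abs(rowSums(wn$w) - 1)), 1e-9)
  expect_error(compute_age_weights(M, rep(50, n), preprocess_params()),
               "singular")
})

test_that("age-informative steps out-weigh flat steps across seeded replicates", {
  n <- 100
  wins <- 0L
  reps <- 25L
  for (r in seq_len(reps)) {
    ages <- withr::with_seed(100 + r, runif(n, 20, 80))
    M <- matrix(withr::with_seed(200 + r, rnorm(n * 53200)), n, 53200)
    M[, 11] <- M[, 11] + 0.05 * (ages - 45)   # step A: strong slope
    w <- compute_age_weights(M, ages, preprocess_params())
    if (w$w[1, 11] > w$w[1, 71]) wins <- wins + 1L  # step B: flat
  }
  expect_gte(wins, reps - 1L)
})

test_that("model F-test p-values agree with a permutation oracle", {
  n <- 20
  ages <- withr::with_seed(7, runif(n, 20, 80))
  M <- matrix(withr::with_seed(8, rnorm(n * 53200)), n, 53200)
  M[, 1] <- M[, 1] + 0.012 * (ages - 45)      # modest, mid-range p
  w <- compute_age_weights(M, ages, preprocess_params())
  y <- M[, 1]
  fstat <- function(a) {
    X <- cbind(1, a, a^2)
    rss <- sum(qr.resid(qr(X), y)^2)
    tss <- sum((y - mean(y))^2)
    ((tss - rss) / 2) / (rss / (n - 3))
  }
  f_obs <- fstat(ages)
  perms <- withr::with_seed(9, replicate(4000, fstat(sample(ages))))
  p_perm <- mean(perms >= f_obs)
  expect_lt(abs(w$p[1, 1] - p_perm), 0.05)
})

test_that("feature reduction equals a brute-force dot product oracle", {
  cfg <- generator_config(n_subjects = 1, seed = 51)
  cg <- generate_cohort(cfg)$connectograms[[1]]
  w <- ta_uniform_weights()
  f <- reduce_to_features(cg, w)
  expect_length(f, 532)
  expect_identical(names(f), feature_names())
  # uniform weights give the arithmetic step mean
  expect_equal(unname(f["AF_L.GFA"]), mean(unclass(cg)["AF_L", , "GFA"]),
               tolerance = 1e-12)
  # point mass on step 17 picks out that step's value
  w1 <- w
  w1$w[] <- 0; w1$w[, 18] <- 1
  f1 <- reduce_to_features(cg, w1)
  expect_equal(unname(f1["UF_R.RD"]), unclass(cg)["UF_R", 18, "RD"],
               tolerance = 1e-12)
  # random weights vs explicit per-cell dot product
  w2 <- w
  w2$w[] <- withr::with_seed(3, runif(532 * 100))
  f2 <- reduce_to_features(cg, w2)
  for (cell in c(1, 200, 532)) {
    tr <- sub("\\.[^.]+$", "", feature_names()[cell])
    ix <- sub("^.*\\.", "", feature_names()[cell])
    expect_equal(unname(f2[cell]),
                 sum(w2$w[cell, ] * unclass(cg)[tr, , ix]) /
                   sum(w2$w[cell, ]),
                 tolerance = 1e-12)
  }
  w0 <- w; w0$w[3, ] <- 0
  expect_error(reduce_to_features(cg, w0), "all-zero weight")
})

test_that("the fitted pipeline is order-stable and matches the granular path", {
  cfg <- generator_config(n_subjects = 12, seed = 52)
  coh <- generate_cohort(cfg)
  fp <- fit_feature_pipeline(coh$connectograms, coh$cohort$age)
  feats <- pipeline_features(coh$connectograms, fp)
  expect_identical(dim(feats), c(12L, 532L))
  # granular operations produce the same features
  g <- reduce_to_features(
    apply_normalization(smooth_profiles(coh$connectograms[[7]], fp$params),
                        fp$stats),
    fp$weights)
  expect_equal(g, feats[7, ], tolerance = 1e-12)
  # permuting subject order permutes rows only
  perm <- c(5, 1, 12, 3, 2, 11, 8, 7, 10, 4, 6, 9)
  feats_p <- pipeline_features(coh$connectograms[perm], fp)
  expect_equal(feats_p, feats[perm, ], tolerance = 0)
})
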