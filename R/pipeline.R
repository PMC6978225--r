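#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters plus one global seed; all stage seeds
#' are derived deterministically from the global seed (fixed documented
#' offsets), so a configuration fully determines every artifact byte.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory for stage artifacts.
#' @param generator,preprocess,encoder,age_model,normative,analysis Named
#'   lists overriding individual defaults (see Details in the package
#'   vignette).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(seed = 42L, outdir = "tractage_run",
                       generator = list(), preprocess = list(),
                       encoder = list(), age_model = list(),
                       normative = list(), analysis = list()) {
  merge <- function(defaults, override) {
    bad <- setdiff(names(override), names(defaults))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    utils::modifyList(defaults, override)
  }
  structure(list(
    seed = as.integer(seed), outdir = outdir,
    generator = merge(list(subject_sd = 0.03, step_sd = 0.06,
                           brainage_sd = 5), generator),
    preprocess = merge(list(smooth_sigma = 2, kernel_truncation = 3,
                            boundary_mode = "reflect", pvalue_floor = 1e-300,
                            normalize_weights = TRUE), preprocess),
    encoder = merge(list(enabled = TRUE, hidden_units = 179L,
                         epochs = 1600L, sparsity_target = 0.05,
                         sparsity_weight = 1, l2_weight = 1e-4), encoder),
    age_model = merge(list(kernel = "squared_exponential_plus_noise",
                           n_restarts = 3L), age_model),
    normative = merge(list(method = "quadratic", window = 10), normative),
    analysis = merge(list(adjust = "BH", alpha = 0.05, fraction = 0.05,
                          n_boot = 2000L, outlier_sd = 2.5,
                          outlier_groups = "lmtle"), analysis)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A \code{\link{run_config}}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialization; embedded in every stage log so
#' that downstream stages can refuse artifacts produced under a different
#' configuration.
#'
#' @param config A \code{\link{run_config}}.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

.art <- function(config, name) file.path(config$outdir, name)

.stage_log <- function(config, stage, extra = list()) {
  log <- c(list(stage = stage, config_hash = config_hash(config),
                seed = config$seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(log, .art(config, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(log)
}

.require_stage <- function(config, stage, force = FALSE) {
  logf <- .art(config, paste0(stage, ".json"))
  if (!file.exists(logf))
    stop("missing upstream artifact: run ", stage, " first")
  if (!force) {
    log <- jsonlite::read_json(logf)
    if (!identical(log$config_hash, config_hash(config)))
      stop("artifact from '", stage, "' was produced under a different ",
           "configuration; rerun it or use force = TRUE")
  }
  invisible(TRUE)
}

#' Pipeline stages
#'
#' Each stage reads its upstream artifacts from \code{config$outdir},
#' writes its own artifacts plus a JSON log (parameters, seed, config
#' hash), and refuses upstream artifacts produced under a different
#' configuration unless \code{force = TRUE}.
#' \code{stage_simulate} draws the six-cohort study suite;
#' \code{stage_preprocess} fits the feature pipeline on the training cohort
#' and reduces every cohort to 532 features; \code{stage_train} trains the
#' autoencoder (unless pass-through) and the Gaussian-process age model and
#' cross-validates it; \code{stage_predict} predicts age and PAD for every
#' cohort; \code{stage_normative} fits the normative model on the normative
#' cohort; \code{stage_analyze} runs the group, attribution and clinical
#' analyses; \code{stage_report} assembles a plain-text report.
#'
#' @param config A \code{\link{run_config}}.
#' @param force Skip the config-hash check on upstream artifacts.
#' @return Each stage invisibly returns its main in-memory result.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_simulate <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  g <- config$generator
  suite <- make_study_suite(seed = config$seed, subject_sd = g$subject_sd,
                            step_sd = g$step_sd, brainage_sd = g$brainage_sd)
  saveRDS(suite, .art(config, "suite.rds"))
  write_cohort(suite_cohort_table(suite), .art(config, "cohort.csv"))
  .stage_log(config, "simulate",
             list(n = vapply(suite, function(x) nrow(x$cohort), numeric(1))))
  invisible(suite)
}

#' @rdname stages
#' @export
stage_preprocess <- function(config, force = FALSE) {
  .require_stage(config, "simulate", force)
  suite <- readRDS(.art(config, "suite.rds"))
  pp <- do.call(preprocess_params, config$preprocess)
  fp <- fit_feature_pipeline(suite$training$connectograms,
                             suite$training$cohort$age, pp)
  saveRDS(fp, .art(config, "pipeline.rds"))
  for (nm in names(suite)) {
    feats <- pipeline_features(suite[[nm]]$connectograms, fp)
    df <- data.frame(subject_id = rownames(feats), feats,
                     check.names = FALSE)
    data.table::fwrite(df, .art(config, sprintf("features_%s.csv", nm)))
  }
  .stage_log(config, "preprocess", list(n_features = .TA$n_cells))
  invisible(fp)
}

.read_features <- function(config, cohort_name) {
  f <- .art(config, sprintf("features_%s.csv", cohort_name))
  df <- data.table::fread(f, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname stages
#' @export
stage_train <- function(config, force = FALSE) {
  .require_stage(config, "preprocess", force)
  suite <- readRDS(.art(config, "suite.rds"))
  tr <- .read_features(config, "training")
  enc_cfg <- config$encoder
  if (isTRUE(enc_cfg$enabled)) {
    spec <- autoencoder_spec(hidden_units = enc_cfg$hidden_units,
                             epochs = enc_cfg$epochs,
                             sparsity_target = enc_cfg$sparsity_target,
                             sparsity_weight = enc_cfg$sparsity_weight,
                             l2_weight = enc_cfg$l2_weight,
                             seed = config$seed + 21L)
    ae <- train_autoencoder(tr, spec)
    ctr <- encode(ae, tr)
  } else {
    ae <- NULL
    ctr <- tr
  }
  am_spec <- age_model_spec(kernel = config$age_model$kernel,
                            n_restarts = config$age_model$n_restarts,
                            seed = config$seed + 22L)
  ages <- suite$training$cohort$age
  sexes <- suite$training$cohort$sex
  cv <- cross_validate_10fold(ctr, sexes, ages, am_spec,
                              seed = config$seed + 23L)
  gp <- train_age_model(ctr, sexes, ages, am_spec)
  model <- list(autoencoder = ae, age_model = gp,
                feature_dim = ncol(ctr),
                cv_metrics = cv$metrics,
                residual_age_r = residual_age_correlation(cv$predictions))
  saveRDS(model, .art(config, "model.rds"))
  data.table::fwrite(data.frame(metric = c("cv_r", "cv_rmse", "cv_mae",
                                           "residual_age_r"),
                                value = c(cv$metrics$r, cv$metrics$rmse,
                                          cv$metrics$mae,
                                          model$residual_age_r)),
                     .art(config, "cv_metrics.csv"))
  .stage_log(config, "train",
             list(feature_dim = ncol(ctr),
                  reconstruction_rate =
                    if (!is.null(ae)) ae$report$reconstruction_rate else NA))
  invisible(model)
}

#' @rdname stages
#' @export
stage_predict <- function(config, force = FALSE) {
  .require_stage(config, "train", force)
  suite <- readRDS(.art(config, "suite.rds"))
  model <- readRDS(.art(config, "model.rds"))
  preds <- lapply(names(suite), function(nm) {
    feats <- .read_features(config, nm)
    if (!is.null(model$autoencoder)) feats <- encode(model$autoencoder, feats)
    tab <- predict_age(model$age_model, feats, suite[[nm]]$cohort$sex,
                       suite[[nm]]$cohort$age,
                       subject_ids = suite[[nm]]$cohort$subject_id)
    tab$group <- nm
    tab
  })
  preds <- do.call(rbind, preds)
  data.table::fwrite(preds, .art(config, "predictions.csv"))
  .stage_log(config, "predict", list(n = nrow(preds)))
  invisible(preds)
}

#' @rdname stages
#' @export
stage_normative <- function(config, force = FALSE) {
  .require_stage(config, "preprocess", force)
  suite <- readRDS(.art(config, "suite.rds"))
  feats <- .read_features(config, "normative")
  np <- fit_normative(feats, suite$normative$cohort,
                      method = config$normative$method,
                      window = config$normative$window)
  saveRDS(np, .art(config, "normative.rds"))
  .stage_log(config, "normative", list(n = np$n, method = np$method))
  invisible(np)
}

#' @rdname stages
#' @export
stage_analyze <- function(config, force = FALSE) {
  .require_stage(config, "predict", force)
  .require_stage(config, "normative", force)
  suite <- readRDS(.art(config, "suite.rds"))
  np <- readRDS(.art(config, "normative.rds"))
  preds <- data.table::fread(.art(config, "predictions.csv"),
                             data.table = FALSE)
  an <- config$analysis
  study <- preds[preds$group %in% c("controls", "lmtle", "rmtle"), ]
  demo <- suite_cohort_table(suite, c("controls", "lmtle", "rmtle"))
  demo <- demo[match(study$subject_id, demo$subject_id), ]

  anc <- ancova_pad(study$pad, study$group, demo$age, demo$sex,
                    demo$handedness)
  ph <- posthoc_pairwise(study$pad, study$group)
  data.table::fwrite(data.frame(F = anc$F, p = anc$p, df1 = anc$df[1],
                                df2 = anc$df[2]), .art(config, "ancova.csv"))
  data.table::fwrite(ph, .art(config, "posthoc.csv"))

  results <- list(ancova = anc, posthoc = ph)
  for (grp in c("lmtle", "rmtle")) {
    feats <- .read_features(config, grp)
    z <- zscore_cohort(feats, suite[[grp]]$cohort, np)
    data.table::fwrite(data.frame(subject_id = rownames(z), z,
                                  check.names = FALSE),
                       .art(config, sprintf("zscores_%s.csv", grp)))
    mu <- mass_univariate_z(z, adjust = an$adjust, alpha = an$alpha)
    data.table::fwrite(mu, .art(config, sprintf("mass_univariate_%s.csv",
                                                grp)))
    sel <- select_top_features(mu, fraction = an$fraction)
    att <- pca_attribution(z[, sel, drop = FALSE],
                           study$pad[study$group == grp])
    data.table::fwrite(data.frame(tract = names(att$tract_contributions),
                                  contribution_pct =
                                    as.numeric(att$tract_contributions)),
                       .art(config, sprintf("tract_contributions_%s.csv",
                                            grp)))
    pad_g <- study$pad[study$group == grp]
    outlier <- if (grp %in% an$outlier_groups) an$outlier_sd else Inf
    cc <- clinical_correlations(pad_g, suite[[grp]]$cohort,
                                normality_alpha = an$alpha,
                                outlier_sd = outlier)
    boot <- lapply(seq_len(nrow(cc)), function(i) {
      v <- cc$variable[i]
      conf <- data.frame(age = suite[[grp]]$cohort$age,
                         sex = .encode_sex(suite[[grp]]$cohort$sex),
                         n_aed_classes = suite[[grp]]$cohort$n_aed_classes)
      bootstrap_correlation(pad_g, suite[[grp]]$cohort[[v]], conf,
                            n_boot = an$n_boot,
                            seed = config$seed + 24L + i,
                            method = cc$method[i])
    })
    cc$ci_lower <- vapply(boot, `[[`, numeric(1), "ci_lower")
    cc$ci_upper <- vapply(boot, `[[`, numeric(1), "ci_upper")
    data.table::fwrite(cc, .art(config,
                                sprintf("clinical_correlations_%s.csv", grp)))
    results[[grp]] <- list(
      mass_univariate = mu,
      n_significant_cells = sum(mu$significant, na.rm = TRUE),
      n_significant_tracts =
        length(unique(mu$tract[mu$significant %in% TRUE])),
      selected = sel, attribution = att, clinical = cc)
  }
  saveRDS(results, .art(config, "analysis.rds"))
  .stage_log(config, "analyze", list())
  invisible(results)
}

#' @rdname stages
#' @export
stage_report <- function(config, force = FALSE) {
  .require_stage(config, "analyze", force)
  model <- readRDS(.art(config, "model.rds"))
  results <- readRDS(.art(config, "analysis.rds"))
  preds <- data.table::fread(.art(config, "predictions.csv"),
                             data.table = FALSE)
  study <- preds[preds$group %in% c("controls", "lmtle", "rmtle"), ]
  pad_means <- tapply(study$pad, study$group, mean)
  lines <- c(
    "White matter brain age analysis report",
    "======================================",
    sprintf("compact feature dimension: %d", model$feature_dim),
    sprintf("10-fold CV: r = %.3f, RMSE = %.2f y, MAE = %.2f y",
            model$cv_metrics$r, model$cv_metrics$rmse, model$cv_metrics$mae),
    sprintf("residual-age correlation (training CV): r = %.3f",
            model$residual_age_r),
    "",
    "Group PAD means (years):",
    sprintf("  %-9s %6.2f", names(pad_means), pad_means),
    sprintf("ANCOVA group effect: F(%d,%d) = %.3f, p = %.3g",
            results$ancova$df[1], results$ancova$df[2], results$ancova$F,
            results$ancova$p),
    "",
    "Top contributing tracts (right-lateralized patient group):",
    sprintf("  %-24s %5.1f%%",
            utils::head(names(results$rmtle$attribution$tract_contributions),
                        5),
            utils::head(as.numeric(
              results$rmtle$attribution$tract_contributions), 5)),
    "",
    "Clinical correlations (right-lateralized patient group):",
    sprintf("  %-20s %s r = %+.3f, p = %.3g",
            results$rmtle$clinical$variable, results$rmtle$clinical$method,
            results$rmtle$clinical$r, results$rmtle$clinical$p)
  )
  writeLines(lines, .art(config, "report.txt"))
  .stage_log(config, "report", list())
  invisible(lines)
}

#' Run the full pipeline end to end
#'
#' Executes simulate, preprocess, train, predict, normative, analyze and
#' report in order and returns a headline summary.
#'
#' @param config A \code{\link{run_config}}.
#' @return List with \code{cv_metrics}, \code{test_metrics},
#'   \code{feature_dim}, \code{reconstruction_rate}, \code{pad_means},
#'   \code{ancova}, \code{top_tracts}, \code{clinical} (per patient group),
#'   \code{outdir}.
#' @export
run_end_to_end <- function(config = run_config()) {
  stage_simulate(config)
  stage_preprocess(config)
  model <- stage_train(config)
  preds <- stage_predict(config)
  stage_normative(config)
  results <- stage_analyze(config)
  stage_report(config)
  study <- preds[preds$group %in% c("controls", "lmtle", "rmtle"), ]
  test <- preds[preds$group == "testing", ]
  list(cv_metrics = model$cv_metrics,
       test_metrics = model_metrics(test$chronological_age,
                                    test$predicted_age),
       feature_dim = model$feature_dim,
       reconstruction_rate = if (!is.null(model$autoencoder))
         model$autoencoder$report$reconstruction_rate else NA,
       pad_means = tapply(study$pad, study$group, mean),
       ancova = results$ancova,
       top_tracts = utils::head(
         names(results$rmtle$attribution$tract_contributions), 5),
       clinical = list(lmtle = results$lmtle$clinical,
                       rmtle = results$rmtle$clinical),
       outdir = config$outdir)
}
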