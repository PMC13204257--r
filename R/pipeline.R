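# Pipeline orchestration: reproducible stage commands writing standard
# formats (WAV recordings, CSV tables, JSON reports), each idempotent
# given identical inputs and configuration. These functions, together
# with the thin command-line wrapper in inst/cli/carotidscreen.R, are the
# pipeline's operational surface.

#' Assemble a full run configuration
#'
#' Nested sections mirror each stage's parameters; the resolved
#' configuration is written next to every run's outputs.
#'
#' @param synth A [cohort_config()].
#' @param preprocess A [preprocess_params()] or `NULL` to adapt the
#'   decimation factor to the cohort's sampling rate.
#' @param morse A [morse_params()].
#' @param features A [feature_config()].
#' @param model List with `test_frac`, `k`, `lambda`, `sens_min`.
#' @param seed Master seed (propagated to stages that accept one).
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = cohort_config(),
                       preprocess = NULL,
                       morse = morse_params(),
                       features = feature_config(),
                       model = list(test_frac = 0.15, k = 5, lambda = 1,
                                    sens_min = 0.90),
                       seed = 1L) {
  structure(list(synth = synth, preprocess = preprocess, morse = morse,
                 features = features, model = model,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Top-level keys override the corresponding [run_config()] defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- run_config()
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$synth))
    cfg$synth <- do.call(cohort_config,
                         utils::modifyList(list(seed = cfg$seed), raw$synth))
  if (!is.null(raw$preprocess))
    cfg$preprocess <- do.call(preprocess_params, raw$preprocess)
  if (!is.null(raw$morse)) cfg$morse <- do.call(morse_params, raw$morse)
  if (!is.null(raw$features)) cfg$features <- do.call(feature_config,
                                                      raw$features)
  if (!is.null(raw$model)) cfg$model <- utils::modifyList(cfg$model,
                                                          raw$model)
  cfg
}

write_resolved_config <- function(config, out_dir) {
  jsonlite::write_json(lapply(unclass(config), unclass),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Simulate a cohort and write it to disk
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The cohort directory path, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$synth)
  write_cohort(cohort$recordings, cohort$truth, out_dir,
               config = config$synth)
  write_resolved_config(config, out_dir)
  message("simulate: ", length(cohort$recordings), " recordings -> ",
          out_dir)
  invisible(out_dir)
}

#' Preprocess a cohort and extract the feature table
#' @param cohort_dir Directory written by [cmd_simulate()].
#' @param config A [run_config()].
#' @param out_path Output CSV path.
#' @return The feature table, invisibly (also written to `out_path`).
#' @export
cmd_features <- function(cohort_dir, config, out_path) {
  cohort <- read_cohort(cohort_dir)
  fs <- cohort$recordings[[1]]$fs
  pp <- if (is.null(config$preprocess)) auto_decim_params(fs) else
    config$preprocess
  segsets <- lapply(cohort$recordings, preprocess_recording, params = pp)
  feats <- feature_table(segsets, morse = config$morse,
                         config = config$features)
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_full_precision(feats), out_path,
                   row.names = FALSE, quote = FALSE)
  message("features: ", nrow(feats), " segments x ",
          length(feature_columns(feats)), " features -> ", out_path)
  invisible(feats)
}

# serialize numerics at full (round-trip) precision
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format(df[[j]], digits = 17,
                                              trim = TRUE)
  }
  df
}

#' Univariate screening stage
#' @param features_path Feature CSV from [cmd_features()] (or a
#'   data.frame).
#' @param config A [run_config()].
#' @param out_dir Directory for `ranking.csv` and `group_tests.csv`.
#' @return List with `ranking` and `tests`, invisibly.
#' @export
cmd_screen <- function(features_path, config, out_dir) {
  feats <- if (is.data.frame(features_path)) features_path else
    utils::read.csv(features_path, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ranking <- univariate_cv_rank(feats, k = config$model$k,
                                seed = config$seed)
  agg <- aggregate_patient_side(feats)
  tests <- mannwhitney_bh(agg)
  utils::write.csv(format_full_precision(ranking),
                   file.path(out_dir, "ranking.csv"), row.names = FALSE)
  utils::write.csv(format_full_precision(tests),
                   file.path(out_dir, "group_tests.csv"), row.names = FALSE)
  message("screen: ranked ", nrow(ranking), " features -> ", out_dir)
  invisible(list(ranking = ranking, tests = tests))
}

#' Train, threshold and evaluate stage
#' @param features_path Feature CSV or data.frame.
#' @param config A [run_config()].
#' @param out_dir Directory for the model JSON, evaluation report and
#'   curve CSVs.
#' @return The `screen_fit`, invisibly.
#' @export
cmd_train_eval <- function(features_path, config, out_dir) {
  feats <- if (is.data.frame(features_path)) features_path else
    utils::read.csv(features_path, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- train_evaluate(feats,
                        feature_cols = config$features$core_set,
                        test_frac = config$model$test_frac,
                        k = config$model$k, lambda = config$model$lambda,
                        sens_min = config$model$sens_min,
                        seed = config$seed)
  model_out <- list(coef = as.list(stats::setNames(fit$model$coef,
                                                   fit$feature_cols)),
                    intercept = fit$model$intercept,
                    center = as.list(stats::setNames(fit$model$center,
                                                     fit$feature_cols)),
                    scale = as.list(stats::setNames(fit$model$scale,
                                                    fit$feature_cols)),
                    lambda = fit$lambda,
                    threshold = unclass(fit$threshold))
  jsonlite::write_json(model_out, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- list(
    threshold = unclass(fit$threshold),
    test_segment = fit$test$segment[c("auroc", "aupr", "sensitivity",
                                      "specificity", "precision", "f1",
                                      "accuracy", "n")],
    test_side = fit$test$side[c("auroc", "aupr", "sensitivity",
                                "specificity", "precision", "f1",
                                "accuracy", "n")],
    oof_side_auroc = auroc(fit$oof$side$prob, fit$oof$side$label),
    n_train_groups = length(fit$plan$train_groups),
    n_test_groups = length(fit$plan$test_groups))
  jsonlite::write_json(report, file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$test$side$roc, file.path(out_dir, "roc_side.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$test$side$pr, file.path(out_dir, "pr_side.csv"),
                   row.names = FALSE)
  message("train-eval: tau = ", format(fit$threshold$tau),
          ", test side AUROC = ", format(fit$test$side$auroc), " -> ",
          out_dir)
  invisible(fit)
}

#' Attribution stage
#' @param fit A `screen_fit` from [cmd_train_eval()].
#' @param features_path Feature CSV or data.frame (training rows are
#'   explained).
#' @param out_dir Directory for `attributions.csv` and `importance.csv`.
#' @return List with `attr` and `importance`, invisibly.
#' @export
cmd_explain <- function(fit, features_path, out_dir) {
  feats <- if (is.data.frame(features_path)) features_path else
    utils::read.csv(features_path, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- feats[feats$group_key %in% fit$plan$train_groups, , drop = FALSE]
  attr <- linear_shap(fit$model, tr[, fit$feature_cols, drop = FALSE])
  imp <- global_importance(attr)
  phi <- as.data.frame(attr$phi)
  colnames(phi) <- paste0("phi_", fit$feature_cols)
  out <- cbind(tr[, c("patient_id", "side", "group_key", "segment_index",
                      "label")],
               base_value = attr$base_value,
               predicted_logodds = attr$predicted_logodds, phi)
  utils::write.csv(format_full_precision(out),
                   file.path(out_dir, "attributions.csv"),
                   row.names = FALSE)
  utils::write.csv(format_full_precision(imp),
                   file.path(out_dir, "importance.csv"), row.names = FALSE)
  message("explain: ", nrow(out), " segments attributed -> ", out_dir)
  invisible(list(attr = attr, importance = imp))
}

#' Run the full pipeline
#'
#' simulate -> features -> screen -> train-eval -> explain, writing the
#' complete artifact tree under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return List with the feature table, screening output, fit and
#'   attribution summary, invisibly.
#' @export
cmd_run_all <- function(config, out_dir) {
  cohort_dir <- file.path(out_dir, "cohort")
  cmd_simulate(config, cohort_dir)
  feats <- cmd_features(cohort_dir, config,
                        file.path(out_dir, "features.csv"))
  screen <- cmd_screen(feats, config, file.path(out_dir, "screen"))
  fit <- cmd_train_eval(feats, config, file.path(out_dir, "model"))
  expl <- cmd_explain(fit, feats, file.path(out_dir, "explain"))
  write_resolved_config(config, out_dir)
  invisible(list(features = feats, screen = screen, fit = fit,
                 explain = expl))
}

#' @rdname cmd_run_all
#' @export
run_pipeline <- cmd_run_all
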