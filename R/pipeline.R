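# One global seed fans out to per-stage seeds through a fixed affine rule,
# so any stage can be rerun in isolation with the same stream. Kept well
# below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, split = 2L, ensemble = 3L, importance = 4L,
               kfold = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]] * 9973) %%
               2147483000)
}

# Stable short hash of the run configuration (md5 of its serialized form).
config_hash <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  obj <- list(...)
  txt <- paste(utils::capture.output(utils::str(obj, give.attr = FALSE)),
               collapse = "\n")
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Run one experiment end to end
#'
#' Drives the full protocol for one experiment and feature set:
#' generate (or accept) a cohort, censor converters at conversion, make the
#' balanced covariate-matched train/test split, fit per-measure trajectory
#' models on the training subjects only, build the feature table (held-out
#' subjects get BLUP features under the train-fitted models), tune and train
#' the soft-voting ensemble, evaluate on the held-out test set, and compute
#' permutation feature importance on it.
#'
#' @param experiment \code{"hc-cmci"} (stable controls vs converters to MCI)
#'   or \code{"smci-cad"} (stable MCI vs converters to AD).
#' @param feature_set \code{"cog"} (trajectory features of the three
#'   cognitive tests) or \code{"cog+mri"} (plus the six MRI measures).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param config Cohort configuration used when \code{cohort} is NULL.
#' @param cohort Optional pre-built long-format cohort (e.g. from
#'   \code{\link{read_cohort}}); when supplied, \code{config} is ignored for
#'   generation.
#' @param grids Hyperparameter grids, see \code{\link{default_grids}}.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param importance_trials Shuffles per feature for permutation importance.
#' @param out_dir Optional directory; when given, the feature table, split
#'   report, metrics, confusion matrix, CV log and importance table are
#'   written there as CSV, each stamped with the run's config hash.
#' @return List with \code{report} (\code{classification_report}),
#'   \code{importance}, \code{ensemble}, \code{split}, \code{features},
#'   \code{models}, \code{config_hash}.
#' @export
report_experiment <- function(experiment, feature_set = "cog+mri",
                              seed = 1L, config = default_config(),
                              cohort = NULL, grids = default_grids(),
                              test_fraction = 0.2, importance_trials = 5,
                              out_dir = NULL) {
  experiment_groups(experiment)          # validate tags early
  feature_set_measures(feature_set)
  hash <- config_hash(experiment = experiment, feature_set = feature_set,
                      seed = seed, test_fraction = test_fraction,
                      config = if (is.null(cohort)) unclass(config) else "external",
                      grids = grids)
  if (is.null(cohort)) {
    config$seed <- stage_seed(seed, "cohort")
    cohort <- generate_cohort(config)
  }
  censored <- censor_post_conversion(cohort)
  groups <- experiment_groups(experiment)
  summary <- subject_summary(censored[censored$subgroup %in% groups, ])
  summary$label <- as.integer(summary$subgroup == groups[["pos"]])
  split <- make_split(summary, test_fraction = test_fraction,
                      seed = stage_seed(seed, "split"))
  train_rows <- censored[censored$subject_id %in% split$train_ids, ]
  models <- fit_trajectory_models(train_rows, feature_set)
  features <- build_feature_table(
    censored[censored$subject_id %in% c(split$train_ids, split$test_ids), ],
    models, experiment = experiment, feature_set = feature_set,
    train_ids = split$train_ids
  )
  fc <- attr(features, "feature_cols")
  train_feat <- features[features$subject_id %in% split$train_ids, ]
  test_feat <- features[features$subject_id %in% split$test_ids, ]
  for (tb in c("train_feat", "test_feat")) {
    t0 <- get(tb)
    attr(t0, "feature_cols") <- fc
    attr(t0, "experiment") <- experiment
    attr(t0, "feature_set") <- feature_set
    assign(tb, t0)
  }
  ensemble <- train_ensemble(train_feat, grids = grids,
                             seed = stage_seed(seed, "ensemble"))
  pred <- predict_soft_vote(ensemble, test_feat)
  report <- evaluate(pred, test_feat$label)
  importance <- permutation_importance(
    ensemble, test_feat, n_trials = importance_trials,
    seed = stage_seed(seed, "importance")
  )
  result <- list(report = report, importance = importance,
                 ensemble = ensemble, split = split, features = features,
                 models = models, predictions = pred, config_hash = hash,
                 experiment = experiment, feature_set = feature_set,
                 seed = seed)
  if (!is.null(out_dir)) {
    write_experiment_artifacts(result, out_dir)
  }
  result
}

write_experiment_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(path) {
    con <- file(path, "a")
    on.exit(close(con))
    writeLines(paste0("# config_hash=", result$config_hash,
                      " seed=", result$seed), con)
  }
  stem <- file.path(out_dir, paste0(result$experiment, "_",
                                    gsub("\\+", "", result$feature_set)))
  write_feature_table(result$features, paste0(stem, "_features.csv"))
  write_report(result$report, stem)
  write.csv(as.data.frame(result$importance),
            paste0(stem, "_importance.csv"), row.names = FALSE)
  write.csv(result$ensemble$cv_log, paste0(stem, "_cvlog.csv"),
            row.names = FALSE)
  write.csv(result$split$report, paste0(stem, "_split.csv"),
            row.names = FALSE)
  for (suffix in c("_features.csv", "_metrics.csv", "_confusion.csv",
                   "_importance.csv", "_cvlog.csv", "_split.csv")) {
    stamp(paste0(stem, suffix))
  }
  invisible(stem)
}

#' Run the pipeline from a run configuration
#'
#' Thin wrapper around \code{\link{report_experiment}} for scripted use
#' (the \code{inst/cli/trajex.R} entry point calls it). Validates the run
#' configuration, resolves the cohort source (synthetic config or CSV
#' path), and writes all artifacts to the output directory.
#'
#' @param run_config List with elements \code{experiment}
#'   (\code{"hc-cmci"}/\code{"smci-cad"}), \code{feature_set}
#'   (\code{"cog"}/\code{"cog+mri"}), \code{seed}, \code{test_fraction},
#'   \code{out_dir}, and either \code{cohort_csv} (path) or
#'   \code{synthetic = TRUE} with optional \code{config_file} (flat-YAML
#'   cohort config) ; optional \code{compact_grids} (logical).
#' @return The \code{\link{report_experiment}} result, invisibly.
#' @export
run_pipeline <- function(run_config) {
  required <- c("experiment", "feature_set", "seed")
  known <- c(required, "test_fraction", "out_dir", "cohort_csv",
             "synthetic", "config_file", "compact_grids",
             "importance_trials")
  unknown <- setdiff(names(run_config), known)
  problems <- character(0)
  if (length(unknown)) {
    problems <- c(problems, paste("unknown config keys:",
                                  paste(unknown, collapse = ", ")))
  }
  for (f in required) {
    if (is.null(run_config[[f]])) problems <- c(problems,
                                                paste("missing key:", f))
  }
  if (!is.null(run_config$experiment) &&
      !run_config$experiment %in% c("hc-cmci", "smci-cad")) {
    problems <- c(problems, paste0("invalid experiment '",
                                   run_config$experiment,
                                   "'; valid tags: hc-cmci, smci-cad"))
  }
  if (!is.null(run_config$feature_set) &&
      !run_config$feature_set %in% c("cog", "cog+mri")) {
    problems <- c(problems, paste0("invalid feature_set '",
                                   run_config$feature_set,
                                   "'; valid tags: cog, cog+mri"))
  }
  if (is.null(run_config$cohort_csv) && !isTRUE(run_config$synthetic)) {
    problems <- c(problems, "need cohort_csv or synthetic=TRUE")
  }
  if (length(problems)) {
    stop(paste(problems, collapse = "; "), call. = FALSE)
  }
  cohort <- if (!is.null(run_config$cohort_csv)) {
    read_cohort(run_config$cohort_csv)
  } else NULL
  config <- if (!is.null(run_config$config_file)) {
    read_config(run_config$config_file)
  } else default_config()
  grids <- default_grids(compact = isTRUE(run_config$compact_grids))
  result <- report_experiment(
    experiment = run_config$experiment,
    feature_set = run_config$feature_set,
    seed = run_config$seed,
    config = config, cohort = cohort, grids = grids,
    test_fraction = if (is.null(run_config$test_fraction)) 0.2 else
      run_config$test_fraction,
    importance_trials = if (is.null(run_config$importance_trials)) 5 else
      run_config$importance_trials,
    out_dir = run_config$out_dir
  )
  invisible(result)
}
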