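experiment_groups <- function(experiment) {
  switch(experiment,
    "hc-cmci"  = c(neg = "HC", pos = "cMCI"),
    "smci-cad" = c(neg = "sMCI", pos = "cAD"),
    stop("unknown experiment '", experiment,
         "'; valid tags: hc-cmci, smci-cad", call. = FALSE)
  )
}

feature_set_measures <- function(feature_set, specs = measure_specs()) {
  switch(feature_set,
    "cog" = specs[specs$modality == "cognitive", , drop = FALSE],
    "cog+mri" = specs,
    stop("unknown feature set '", feature_set,
         "'; valid tags: cog, cog+mri", call. = FALSE)
  )
}

#' Fit trajectory models for a set of measures
#'
#' Convenience wrapper fitting \code{\link{fit_trajectory_model}} for every
#' measure in a feature set on the training subjects only.
#'
#' @param train_cohort Censored long-format rows of the training subjects.
#' @param feature_set \code{"cog"} or \code{"cog+mri"}.
#' @return Named list of \code{\link{trajectory_model}}s.
#' @export
fit_trajectory_models <- function(train_cohort, feature_set = "cog+mri") {
  specs <- feature_set_measures(feature_set)
  models <- lapply(seq_len(nrow(specs)), function(i) {
    fit_trajectory_model(train_cohort, specs[i, ])
  })
  names(models) <- specs$measure
  models
}

#' Assemble the per-subject feature table
#'
#' One row per subject of the experiment's two subgroups. For each measure
#' in the feature set the columns are \code{<measure>_rslope} (the BLUP
#' random slope \eqn{b_{1i}}), \code{<measure>_quad} (\eqn{b_{2i}}, order-2
#' measures only), \code{<measure>_dev} and \code{<measure>_dslope},
#' followed by \code{sex} (0 = male, 1 = female) and \code{current_age}
#' (age at the subject's last retained visit in either modality). The label
#' is 0 for the stable group and 1 for the converter group.
#'
#' Censoring must already have been applied (\code{\link{censor_post_conversion}}),
#' so for converters every feature uses strictly pre-conversion visits and
#' \code{current_age} is the age at the last visit before conversion.
#' Random effects for every subject — training or held-out — are computed
#' with \code{\link{predict_random_effects}} under the train-fitted models,
#' so a subject's features never depend on any other subject's data beyond
#' the training fit.
#'
#' A converter censored down to a single visit in one modality has no
#' endpoint slope there; those \code{_dslope} cells are imputed with the
#' median over training-subject rows (\code{train_ids}; all rows if
#' omitted). Subjects with no usable measure at all are dropped with a
#' message.
#'
#' @param cohort Censored long-format cohort (training and test subjects).
#' @param models Named list of \code{\link{trajectory_model}}s covering the
#'   feature set (fitted on training subjects only).
#' @param experiment \code{"hc-cmci"} or \code{"smci-cad"}.
#' @param feature_set \code{"cog"} or \code{"cog+mri"}.
#' @param train_ids Subject ids forming the training set, used for d-slope
#'   median imputation.
#' @return Data.frame with \code{subject_id}, \code{label}, the feature
#'   columns (attribute \code{"feature_cols"}), and attributes recording the
#'   experiment and feature set.
#' @export
build_feature_table <- function(cohort, models, experiment,
                                feature_set = "cog+mri", train_ids = NULL) {
  groups <- experiment_groups(experiment)
  specs <- feature_set_measures(feature_set)
  missing_models <- setdiff(specs$measure, names(models))
  if (length(missing_models)) {
    stop("no fitted model for measure(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  d <- cohort[cohort$subgroup %in% groups, , drop = FALSE]
  ids <- unique(d$subject_id)

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- d[d$subject_id == ids[i], , drop = FALSE]
    feats <- list(subject_id = ids[i],
                  label = as.integer(sub$subgroup[1] == groups[["pos"]]))
    usable <- FALSE
    for (j in seq_len(nrow(specs))) {
      sp <- specs[j, ]
      m <- sp$measure
      series <- measure_series(sub[, c("age", "measure", "value", "etiv")], sp)
      # measure_series already normalized; hand the model pre-normalized data
      mdl <- models[[m]]
      mdl_raw <- mdl; mdl_raw$normalize_by_etiv <- FALSE
      if (nrow(series) >= 1L) {
        b <- predict_random_effects(mdl_raw, series)
        feats[[paste0(m, "_rslope")]] <- b[2]
        if (mdl$order == 2L) feats[[paste0(m, "_quad")]] <- b[3]
        feats[[paste0(m, "_dev")]] <- compute_dev(mdl_raw, series)
        usable <- TRUE
      } else {
        feats[[paste0(m, "_rslope")]] <- NA_real_
        if (mdl$order == 2L) feats[[paste0(m, "_quad")]] <- NA_real_
        feats[[paste0(m, "_dev")]] <- NA_real_
      }
      feats[[paste0(m, "_dslope")]] <-
        if (nrow(series) >= 2L) compute_d_slope(series) else NA_real_
    }
    feats$sex <- as.integer(sub$sex[1] == "f")
    feats$current_age <- max(sub$age)
    rows[[i]] <- if (usable) as.data.frame(feats, stringsAsFactors = FALSE)
                 else NULL
    if (!usable) message("dropping subject ", ids[i], ": no usable measures")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  # median-impute missing cells from training rows (d-slope of converters
  # censored to a single visit; rarely rslope/dev when a measure is absent)
  ref <- if (is.null(train_ids)) out else out[out$subject_id %in% train_ids, ]
  feature_cols <- setdiff(names(out), c("subject_id", "label"))
  for (col in feature_cols) {
    nas <- is.na(out[[col]])
    if (any(nas)) out[[col]][nas] <- median(ref[[col]], na.rm = TRUE)
  }
  attr(out, "feature_cols") <- feature_cols
  attr(out, "experiment") <- experiment
  attr(out, "feature_set") <- feature_set
  out
}

#' Write a feature table as CSV
#'
#' Header: \code{subject_id,label,<feature columns...>,sex,current_age}.
#'
#' @param features Feature table from \code{\link{build_feature_table}}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
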