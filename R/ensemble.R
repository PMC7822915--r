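#' Balanced, covariate-matched train/test split
#'
#' Splits subjects into disjoint train and test sets, stratified by class
#' label and sex and matched on age: classes are first balanced to equal
#' size (the larger class is randomly subsampled), the test quota of each
#' class is allocated to sex strata proportionally, and within each
#' label-by-sex stratum the subjects are age-sorted, cut into consecutive
#' age bands, and one subject per band is drawn for the test set — so the
#' train and test age distributions match by construction. Deterministic
#' under \code{seed}.
#'
#' @param subjects Data.frame with one row per subject and columns
#'   \code{subject_id}, \code{label} (0/1), \code{sex} (0/1 or "m"/"f"),
#'   and an age column (\code{age} or \code{current_age}).
#' @param test_fraction Fraction of subjects held out, in (0, 1).
#' @param seed Integer seed.
#' @return An object of class \code{split_spec}: list with
#'   \code{train_ids}, \code{test_ids}, \code{test_fraction}, and a
#'   \code{report} data.frame of per-side class counts, sex counts and age
#'   summaries.
#' @export
make_split <- function(subjects, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  age_col <- intersect(c("age", "current_age", "baseline_age", "last_age"),
                       names(subjects))[1]
  if (is.na(age_col)) stop("subjects needs an age column", call. = FALSE)
  d <- data.frame(subject_id = subjects$subject_id,
                  label = subjects$label,
                  sex = as.character(subjects$sex),
                  age = subjects[[age_col]], stringsAsFactors = FALSE)
  set.seed(seed)

  # balance classes by subsampling the larger one
  n_by_class <- table(d$label)
  if (length(n_by_class) != 2L) stop("labels must be binary", call. = FALSE)
  n_bal <- min(n_by_class)
  kept <- unlist(lapply(split(seq_len(nrow(d)), d$label), function(idx) {
    if (length(idx) > n_bal) sort(sample(idx, n_bal)) else idx
  }), use.names = FALSE)
  d <- d[sort(kept), ]

  test_ids <- character(0)
  for (lab in sort(unique(d$label))) {
    dl <- d[d$label == lab, ]
    target <- round(nrow(dl) * test_fraction)
    # proportional allocation to sex strata, largest remainder
    strata <- split(dl, dl$sex)
    sizes <- vapply(strata, nrow, 1L)
    raw <- sizes / sum(sizes) * target
    quota <- floor(raw)
    rem <- target - sum(quota)
    if (rem > 0) {
      quota[order(raw - quota, decreasing = TRUE)[seq_len(rem)]] <-
        quota[order(raw - quota, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    for (sx in names(strata)) {
      st <- strata[[sx]][order(strata[[sx]]$age), ]
      t_s <- quota[[sx]]
      if (t_s == 0) next
      if (t_s > nrow(st)) {
        stop("stratum label=", lab, " sex=", sx,
             " too small for the requested split", call. = FALSE)
      }
      bounds <- floor(seq(0, nrow(st), length.out = t_s + 1))
      for (b in seq_len(t_s)) {
        band <- (bounds[b] + 1):bounds[b + 1]
        test_ids <- c(test_ids, st$subject_id[sample(band, 1)])
      }
    }
  }
  train_ids <- setdiff(d$subject_id, test_ids)

  side <- ifelse(d$subject_id %in% test_ids, "test", "train")
  report <- do.call(rbind, lapply(split(d, list(side, d$label), drop = TRUE),
                                  function(s) {
    data.frame(side = ifelse(s$subject_id[1] %in% test_ids, "test", "train"),
               label = s$label[1], n = nrow(s),
               n_female = sum(s$sex %in% c("f", "1")),
               age_mean = mean(s$age), age_sd = sd(s$age),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  structure(list(train_ids = sort(train_ids), test_ids = sort(test_ids),
                 test_fraction = test_fraction, report = report),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("Train/test split:", length(x$train_ids), "train,",
      length(x$test_ids), "test (fraction",
      format(x$test_fraction), ")\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out grid search for one learner family
#'
#' For every grid point, scores leave-one-subject-out cross-validated
#' accuracy on the training table: the learner is refitted \eqn{n} times,
#' each time on all subjects but one, and the held-out subject's predicted
#' class is compared with its label. Returns the grid point with the highest
#' LOOCV accuracy (ties resolved in favour of the earliest grid row) and
#' the learner refitted on the full training table at that point.
#'
#' The feature matrix is used as given; standardization for scale-sensitive
#' families is applied by \code{\link{train_ensemble}} before the search
#' (training-set statistics, stored in the ensemble).
#'
#' @param train_features Feature table (rows = training subjects) with
#'   \code{label} and feature columns.
#' @param family One of \code{"logistic"}, \code{"svm"}, \code{"knn"},
#'   \code{"rf"}, \code{"gbm"}.
#' @param grid Data.frame of hyperparameter combinations (one row each);
#'   see \code{\link{default_grids}}.
#' @param seed Integer seed for stochastic learners.
#' @return List with \code{family}, \code{params} (selected row),
#'   \code{cv_accuracy}, \code{cv_table} (grid with accuracies), and
#'   \code{fit} (refit on all training rows).
#' @export
loocv_grid_search <- function(train_features, family, grid, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0L) {
    stop("empty hyperparameter grid for ", family, call. = FALSE)
  }
  feature_cols <- feature_columns(train_features)
  X <- as.matrix(train_features[, feature_cols, drop = FALSE])
  y <- train_features$label
  if (min(table(y)) < 2) {
    stop("need >= 2 subjects per class for LOOCV", call. = FALSE)
  }
  n <- nrow(X)
  accs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    pred <- integer(n)
    for (i in seq_len(n)) {
      fit <- fit_learner(family, params, X[-i, , drop = FALSE], y[-i],
                         seed = seed, probability = FALSE)
      pred[i] <- predict_learner(fit, X[i, , drop = FALSE], type = "class")
    }
    accs[g] <- mean(pred == y)
  }
  best <- which.max(accs)  # ties -> first grid row
  params <- as.list(grid[best, , drop = FALSE])
  final <- fit_learner(family, params, X, y, seed = seed, probability = TRUE)
  list(family = family, params = params, cv_accuracy = accs[best],
       cv_table = cbind(grid, cv_accuracy = accs), fit = final)
}

feature_columns <- function(features) {
  fc <- attr(features, "feature_cols")
  if (is.null(fc)) fc <- setdiff(names(features), c("subject_id", "label"))
  fc
}

#' Train the soft-voting ensemble
#'
#' Tunes each of the five base families (logistic regression, SVM, kNN,
#' random forest, gradient boosting) by \code{\link{loocv_grid_search}} on
#' the training table, refits each at its selected hyperparameters, and
#' combines them with uniform vote weights. Features are standardized to
#' training mean/SD for the scale-sensitive members (logistic, SVM, kNN);
#' the tree ensembles consume raw features. The scaling statistics are
#' stored in the model so test rows are transformed identically.
#'
#' @param train_features Training feature table (\code{label} + feature
#'   columns; attribute \code{feature_cols} respected).
#' @param grids Named list of per-family grids; see
#'   \code{\link{default_grids}}. Families absent from \code{grids} are
#'   omitted from the ensemble (the vote renormalizes).
#' @param seed Integer seed for the stochastic members.
#' @return An object of class \code{ensemble_model}: tuned members, uniform
#'   vote weights, scaling statistics, feature columns, and the per-family
#'   CV log.
#' @export
train_ensemble <- function(train_features, grids = default_grids(),
                           seed = 1L) {
  feature_cols <- feature_columns(train_features)
  X <- as.matrix(train_features[, feature_cols, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  scaled <- train_features
  scaled[, feature_cols] <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  attr(scaled, "feature_cols") <- feature_cols

  members <- list()
  cv_log <- list()
  for (family in names(grids)) {
    tbl <- if (scale_sensitive(family)) scaled else train_features
    tuned <- tryCatch(
      loocv_grid_search(tbl, family, grids[[family]], seed = seed),
      error = function(e) stop("ensemble member '", family, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    members[[family]] <- tuned
    tab <- tuned$cv_table
    param_cols <- setdiff(names(tab), "cv_accuracy")
    cv_log[[family]] <- data.frame(
      family = family,
      params = apply(tab[, param_cols, drop = FALSE], 1, function(r) {
        paste(param_cols, trimws(r), sep = "=", collapse = " ")
      }),
      cv_accuracy = tab$cv_accuracy, stringsAsFactors = FALSE
    )
  }
  w <- rep(1 / length(members), length(members))
  names(w) <- names(members)
  structure(
    list(members = members, weights = w,
         scaling = list(mean = mu, sd = sdv),
         feature_cols = feature_cols,
         feature_set = attr(train_features, "feature_set"),
         experiment = attr(train_features, "experiment"),
         seed = seed,
         cv_log = do.call(rbind, c(cv_log, make.row.names = FALSE))),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Soft-voting ensemble (", length(x$members), " members, ",
      length(x$feature_cols), " features)\n", sep = "")
  for (m in names(x$members)) {
    cat(sprintf("  %-9s w=%.3f LOOCV acc=%.3f  %s\n", m, x$weights[[m]],
                x$members[[m]]$cv_accuracy,
                paste(names(x$members[[m]]$params),
                      unlist(lapply(x$members[[m]]$params, format)),
                      sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Soft-vote prediction
#'
#' The ensemble probability for the positive (converter) class is the
#' weighted mean of the members' probabilities,
#' \eqn{P = \sum_k w_k p_k}, with uniform weights by default. The predicted
#' label is 1 when \eqn{P \ge 0.5} (a tie at exactly 0.5 goes to class 1).
#' Because the weights are a convex combination, \eqn{P} always lies
#' between the smallest and largest member probability.
#'
#' @param ensemble An \code{\link{ensemble_model}}.
#' @param feature_rows Data.frame containing all feature columns the
#'   ensemble was trained on.
#' @return Data.frame with one row per input row: \code{prob} (ensemble
#'   probability of class 1) and \code{label} (0/1).
#' @export
predict_soft_vote <- function(ensemble, feature_rows) {
  missing_cols <- setdiff(ensemble$feature_cols, names(feature_rows))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(feature_rows[, ensemble$feature_cols, drop = FALSE])
  Xs <- sweep(sweep(X, 2, ensemble$scaling$mean), 2, ensemble$scaling$sd, "/")
  P <- rep(0, nrow(X))
  for (m in names(ensemble$members)) {
    Xm <- if (scale_sensitive(m)) Xs else X
    p <- predict_learner(ensemble$members[[m]]$fit, Xm, type = "prob")
    P <- P + ensemble$weights[[m]] * p
  }
  P <- P / sum(ensemble$weights)
  data.frame(prob = P, label = as.integer(P >= 0.5))
}
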