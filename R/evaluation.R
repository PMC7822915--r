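#' Confusion-matrix metrics for binary predictions
#'
#' Standard binary classification metrics with the converter group as the
#' positive class (label 1): accuracy, precision, recall and F1 for class 1,
#' macro-averaged counterparts, the 2x2 confusion matrix (rows = truth,
#' columns = prediction), and the per-true-class misclassification rates
#' (off-diagonal count over row sum).
#'
#' @param predictions Integer 0/1 vector, or the data.frame returned by
#'   \code{\link{predict_soft_vote}} (its \code{label} column is used).
#' @param labels Integer 0/1 vector of true labels, same length.
#' @return Object of class \code{classification_report}: list with
#'   \code{confusion}, \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{macro_precision}, \code{macro_recall}, \code{macro_f1},
#'   \code{misclassification} (named per-class rates), \code{n_test}.
#' @examples
#' evaluate(c(1, 0, 1, 1), c(1, 0, 0, 1))
#' @export
evaluate <- function(predictions, labels) {
  if (is.data.frame(predictions)) predictions <- predictions$label
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (length(predictions) == 0L) stop("empty input", call. = FALSE)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  conf <- matrix(0L, 2, 2,
                 dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  for (t in 0:1) for (p in 0:1) {
    conf[t + 1, p + 1] <- sum(labels == t & predictions == p)
  }
  prf <- function(pos) {
    tp <- conf[pos + 1, pos + 1]
    fp <- sum(conf[, pos + 1]) - tp
    fn <- sum(conf[pos + 1, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    c(precision = precision, recall = recall, f1 = f1)
  }
  pos <- prf(1); neg <- prf(0)
  miscls <- c(`0` = if (sum(conf[1, ]) > 0) conf[1, 2] / sum(conf[1, ]) else NA,
              `1` = if (sum(conf[2, ]) > 0) conf[2, 1] / sum(conf[2, ]) else NA)
  structure(
    list(confusion = conf,
         accuracy = sum(diag(conf)) / sum(conf),
         precision = unname(pos["precision"]),
         recall = unname(pos["recall"]),
         f1 = unname(pos["f1"]),
         macro_precision = mean(c(pos["precision"], neg["precision"])),
         macro_recall = mean(c(pos["recall"], neg["recall"])),
         macro_f1 = mean(c(pos["f1"], neg["f1"])),
         misclassification = miscls,
         n_test = length(labels)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (n =", x$n_test, ")\n")
  cat(sprintf("  accuracy %.3f | class-1 precision %.3f recall %.3f F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  macro    precision %.3f recall %.3f F1 %.3f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write a classification report to CSV files
#'
#' Writes \code{<stem>_metrics.csv} (one metric per row) and
#' \code{<stem>_confusion.csv} (2x2 with labelled rows = truth).
#'
#' @param report A \code{classification_report}.
#' @param stem Output path prefix.
#' @return The metric file path, invisibly.
#' @export
write_report <- function(report, stem) {
  metrics <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1", "macro_precision",
               "macro_recall", "macro_f1", "misclassification_0",
               "misclassification_1", "n_test"),
    value = c(report$accuracy, report$precision, report$recall, report$f1,
              report$macro_precision, report$macro_recall, report$macro_f1,
              report$misclassification[["0"]],
              report$misclassification[["1"]], report$n_test)
  )
  write.csv(metrics, paste0(stem, "_metrics.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$confusion),
            paste0(stem, "_confusion.csv"))
  invisible(paste0(stem, "_metrics.csv"))
}

#' Stratified k-fold robustness of the full pipeline
#'
#' Partitions the training subjects into \code{k} folds stratified by label
#' and sex and spread across the age range (within each label, subjects are
#' age-sorted and dealt to folds cyclically in a seeded random fold order,
#' so per-fold label counts differ by at most one and fold age means and
#' sex ratios match). Inside each fold the \emph{entire} pipeline — grid
#' search and ensemble refit — is run on the remaining folds and scored on
#' the held-out fold, giving a robustness view of the single held-out-test
#' estimate.
#'
#' @param train_features Training feature table.
#' @param k Number of folds (default 15); must not exceed the smaller class
#'   count.
#' @param seed Integer seed.
#' @param grids Per-family grids passed to \code{\link{train_ensemble}}.
#' @return List with \code{mean_accuracy}, \code{sd_accuracy},
#'   \code{fold_accuracies}, and \code{folds} (data.frame subject_id/fold).
#' @export
kfold_robustness <- function(train_features, k = 15, seed = 1L,
                             grids = default_grids()) {
  y <- train_features$label
  if (k > length(y)) {
    stop("k exceeds the number of subjects", call. = FALSE)
  }
  if (k > min(table(y))) {
    warning("k exceeds the smaller class count; folds will not all ",
            "contain both classes", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(nrow(train_features))
  age_col <- intersect(c("current_age", "age"), names(train_features))[1]
  # one global cycle through a seeded fold order; each label (sorted by sex
  # then age) consumes a contiguous run, so per-fold label counts stay
  # within one of proportional and every fold is populated when k <= n
  cycle <- sample(k)
  pos <- 0L
  for (lab in sort(unique(y))) {
    idx <- which(y == lab)
    sex <- train_features$sex[idx]
    if (is.null(sex)) sex <- rep(0L, length(idx))
    age <- if (!is.na(age_col)) train_features[[age_col]][idx] else
      seq_along(idx)
    idx <- idx[order(sex, age)]
    fold[idx] <- cycle[(pos + seq_along(idx) - 1L) %% k + 1L]
    pos <- pos + length(idx)
  }
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- train_features[fold != f, , drop = FALSE]
    te <- train_features[fold == f, , drop = FALSE]
    attr(tr, "feature_cols") <- feature_columns(train_features)
    ens <- train_ensemble(tr, grids = grids, seed = seed)
    pred <- predict_soft_vote(ens, te)
    accs[f] <- mean(pred$label == te$label)
  }
  list(mean_accuracy = mean(accs), sd_accuracy = sd(accs),
       fold_accuracies = accs,
       folds = data.frame(subject_id = train_features$subject_id,
                          fold = fold, stringsAsFactors = FALSE))
}

#' Permutation feature importance (mean decrease accuracy)
#'
#' For each feature column, shuffles the column within the evaluation table
#' (the fitted model is untouched), re-predicts, and records the drop in
#' accuracy relative to the unshuffled baseline; the drop is averaged over
#' \code{n_trials} independent shuffles. A feature the model ignores scores
#' zero in expectation, and a constant column scores exactly zero (every
#' permutation of its values is the identity). Features whose importance SD
#' across trials exceeds the mean are flagged unstable.
#'
#' Importance is computed on the held-out test rows, so it reflects
#' generalization-relevant feature use.
#'
#' @param ensemble A fitted \code{\link{ensemble_model}} (or any object
#'   accepted by \code{\link{predict_soft_vote}}).
#' @param features Feature table to evaluate on (>= 2 rows).
#' @param labels True 0/1 labels; defaults to \code{features$label}.
#' @param n_trials Shuffles per feature (default 5).
#' @param seed Integer seed; shuffles are deterministic given it.
#' @param permute_fun Permutation generator \code{function(n)} returning an
#'   index vector; the default draws a uniform random permutation. Exposed
#'   for testing (e.g. forcing the identity permutation).
#' @return Object of class \code{importance_report}: data.frame with
#'   \code{feature}, \code{importance} (mean accuracy drop), \code{sd},
#'   \code{n_trials}, \code{unstable}.
#' @export
permutation_importance <- function(ensemble, features, labels = NULL,
                                   n_trials = 5, seed = 1L,
                                   permute_fun = NULL) {
  if (nrow(features) < 2L) {
    stop("permutation importance needs >= 2 rows", call. = FALSE)
  }
  if (is.null(labels)) labels <- features$label
  if (is.null(permute_fun)) permute_fun <- function(n) sample.int(n)
  set.seed(seed)
  feature_cols <- ensemble$feature_cols
  base_acc <- mean(predict_soft_vote(ensemble, features)$label == labels)
  n <- nrow(features)
  rows <- lapply(feature_cols, function(col) {
    drops <- vapply(seq_len(n_trials), function(trial) {
      shuffled <- features
      shuffled[[col]] <- shuffled[[col]][permute_fun(n)]
      acc <- mean(predict_soft_vote(ensemble, shuffled)$label == labels)
      base_acc - acc
    }, numeric(1))
    data.frame(feature = col, importance = mean(drops), sd = sd(drops),
               n_trials = n_trials, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$unstable <- out$sd > abs(out$importance)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Permutation importance (mean decrease accuracy,",
      x$n_trials[1], "trials)\n")
  df <- as.data.frame(x)
  df$importance <- sprintf("%.4f", df$importance)
  df$sd <- sprintf("%.4f", df$sd)
  print(df, row.names = FALSE)
  invisible(x)
}
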