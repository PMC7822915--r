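# Internal learner abstraction: five base families behind a uniform
# fit/predict API. All fits are deterministic given `seed`.
#
#   fit_learner(family, params, X, y, seed, probability)
#   predict_learner(fit, X, type = "prob" | "class")
#
# X is a numeric matrix (already standardized by the caller for the
# scale-sensitive families), y an integer 0/1 vector.

learner_families <- function() c("logistic", "svm", "knn", "rf", "gbm")

scale_sensitive <- function(family) family %in% c("logistic", "svm", "knn")

fit_learner <- function(family, params, X, y, seed = 1L,
                        probability = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  obj <- switch(family,
    logistic = {
      if (identical(params$penalty, "none")) {
        df <- data.frame(.y = y, X)
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = df, family = stats::binomial())
        )
        list(kind = "glm", fit = fit, cols = colnames(X))
      } else {
        # glmnet warns about classes below 8 observations; routine in LOOCV
        fit <- withCallingHandlers(
          glmnet::glmnet(X, factor(y, levels = 0:1),
                         family = "binomial", alpha = 0,
                         lambda = params$lambda),
          warning = function(w) {
            if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
        list(kind = "glmnet", fit = fit, lambda = params$lambda)
      }
    },
    svm = {
      gamma <- if (is.null(params$gamma) || is.na(params$gamma)) {
        1 / ncol(X)
      } else {
        params$gamma
      }
      set.seed(seed)  # probability calibration uses internal CV
      fit <- e1071::svm(X, factor(y, levels = 0:1), kernel = params$kernel,
                        cost = params$cost, gamma = gamma,
                        degree = if (is.null(params$degree)) 3 else params$degree,
                        probability = probability)
      list(kind = "svm", fit = fit, probability = probability)
    },
    knn = list(kind = "knn", X = X, y = y, k = params$k,
               metric = params$metric),
    rf = {
      df <- data.frame(.y = factor(y, levels = 0:1), X)
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = params$num.trees,
        max.depth = if (is.null(params$max.depth)) 0 else params$max.depth,
        probability = TRUE, num.threads = 1, seed = seed
      )
      list(kind = "rf", fit = fit, cols = colnames(X))
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth,
                      subsample = params$subsample, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = params$nrounds
      )
      list(kind = "gbm", fit = fit)
    },
    stop("unknown learner family: ", family, call. = FALSE)
  )
  obj$family <- family
  obj$params <- params
  class(obj) <- "trajex_learner"
  obj
}

# Pairwise distances from rows of A to rows of B.
pair_dist <- function(A, B, metric) {
  if (metric == "euclidean") {
    sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(sq, 0))
  } else if (metric == "manhattan") {
    out <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(ncol(A))) {
      out <- out + abs(outer(A[, j], B[, j], "-"))
    }
    out
  } else {
    stop("unknown metric: ", metric, call. = FALSE)
  }
}

predict_learner <- function(fit, X, type = c("prob", "class")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p1 <- switch(fit$kind,
    glm = {
      df <- as.data.frame(X)
      names(df) <- fit$cols
      unname(predict(fit$fit, newdata = df, type = "response"))
    },
    glmnet = drop(predict(fit$fit, newx = X, s = fit$lambda,
                          type = "response")),
    svm = {
      if (fit$probability) {
        pr <- predict(fit$fit, X, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      } else {
        # class-only path for CV scoring (no Platt calibration fitted)
        as.numeric(as.character(predict(fit$fit, X)))
      }
    },
    knn = {
      d <- pair_dist(X, fit$X, fit$metric)
      apply(d, 1, function(row) {
        nn <- order(row)[seq_len(min(fit$k, length(row)))]
        mean(fit$y[nn])
      })
    },
    rf = {
      df <- as.data.frame(X)
      names(df) <- fit$cols
      predict(fit$fit, data = df, num.threads = 1)$predictions[, "1"]
    },
    gbm = predict(fit$fit, X)
  )
  p1 <- unname(as.numeric(p1))
  if (type == "prob") p1 else as.integer(p1 >= 0.5)
}

#' Default hyperparameter grids for the five base learners
#'
#' Small documented grids per family, searched by subject-level
#' leave-one-out CV: regularization (none vs L2 strength) for logistic
#' regression; kernel (radial, polynomial, sigmoid) and cost for the SVM;
#' neighbour count and distance metric (Euclidean, Manhattan) for kNN; tree
#' count and maximum depth for the random forest; learning rate, depth and
#' subsampling for gradient boosting. The grids are deliberately compact —
#' LOOCV refits every grid point once per training subject — and fully
#' configurable: pass any data.frame with the same columns.
#'
#' @param compact If \code{TRUE}, return a one-point grid per family (the
#'   midpoint of the default grid), for fast end-to-end runs where the
#'   search itself is not under study.
#' @return Named list of data.frames, one per family
#'   (\code{logistic}, \code{svm}, \code{knn}, \code{rf}, \code{gbm}).
#' @export
default_grids <- function(compact = FALSE) {
  if (compact) {
    return(list(
      logistic = data.frame(penalty = "l2", lambda = 0.1,
                            stringsAsFactors = FALSE),
      svm = data.frame(kernel = "radial", cost = 1, gamma = NA_real_,
                       stringsAsFactors = FALSE),
      knn = data.frame(k = 7, metric = "euclidean", stringsAsFactors = FALSE),
      rf = data.frame(num.trees = 150, max.depth = 0),
      gbm = data.frame(eta = 0.3, max_depth = 3, subsample = 0.8,
                       nrounds = 40)
    ))
  }
  list(
    logistic = data.frame(penalty = c("none", "l2", "l2"),
                          lambda = c(0, 0.1, 1), stringsAsFactors = FALSE),
    svm = data.frame(kernel = c("radial", "radial", "polynomial", "sigmoid"),
                     cost = c(1, 10, 1, 1), gamma = NA_real_,
                     stringsAsFactors = FALSE),
    knn = data.frame(k = c(5, 11, 5, 11),
                     metric = rep(c("euclidean", "manhattan"), each = 2),
                     stringsAsFactors = FALSE),
    rf = data.frame(num.trees = c(200, 200), max.depth = c(0, 5)),
    gbm = data.frame(eta = c(0.1, 0.3, 0.1, 0.3),
                     max_depth = c(2, 2, 3, 3), subsample = 0.8,
                     nrounds = 40)
  )
}
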