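make_subject_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("P%04d", seq_len(n)),
    label = rep(0:1, length.out = n),
    sex = sample(c("f", "m"), n, replace = TRUE),
    age = rnorm(n, 76, 7),
    stringsAsFactors = FALSE
  )
}

test_that("split is deterministic, disjoint, class-balanced and age-matched", {
  subjects <- make_subject_table(268, seed = 5)
  sp <- make_split(subjects, test_fraction = 0.2, seed = 11)
  expect_s3_class(sp, "split_spec")
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_equal(length(sp$test_ids) + length(sp$train_ids), 268)
  expect_equal(length(sp$test_ids), 54, tolerance = 0.05)

  # equal class counts in the test side
  lab <- subjects$label[match(sp$test_ids, subjects$subject_id)]
  expect_equal(sum(lab == 0), sum(lab == 1))

  # train and test age distributions match
  age_tr <- subjects$age[match(sp$train_ids, subjects$subject_id)]
  age_te <- subjects$age[match(sp$test_ids, subjects$subject_id)]
  expect_lt(abs(mean(age_tr) - mean(age_te)), 2)

  sp2 <- make_split(subjects, test_fraction = 0.2, seed = 11)
  expect_identical(sp[c("train_ids", "test_ids")],
                   sp2[c("train_ids", "test_ids")])
  expect_error(make_split(subjects, test_fraction = 0), "test_fraction")
  expect_error(make_split(subjects, test_fraction = 1), "test_fraction")
})

test_that("unbalanced classes are equalized before splitting", {
  subjects <- make_subject_table(150, seed = 2)
  subjects$label <- c(rep(0, 100), rep(1, 50))
  sp <- make_split(subjects, test_fraction = 0.2, seed = 3)
  side_ids <- c(sp$train_ids, sp$test_ids)
  lab <- subjects$label[match(side_ids, subjects$subject_id)]
  expect_equal(sum(lab == 0), sum(lab == 1))
})

test_that("LOOCV grid search selects within the grid, ties to first row", {
  feats <- make_toy_features(n = 16, separation = 3, seed = 9)
  grid <- data.frame(k = c(3, 5), metric = "euclidean",
                     stringsAsFactors = FALSE)
  res <- loocv_grid_search(feats, "knn", grid, seed = 1)
  expect_true(res$params$k %in% grid$k)
  expect_equal(nrow(res$cv_table), 2)
  expect_true(all(res$cv_table$cv_accuracy >= 0 &
                    res$cv_table$cv_accuracy <= 1))

  # singleton grid: that point is selected and scored
  single <- loocv_grid_search(feats, "logistic",
                              data.frame(penalty = "l2", lambda = 0.1),
                              seed = 1)
  expect_equal(single$params$lambda, 0.1)
  expect_true(is.finite(single$cv_accuracy))
  expect_error(loocv_grid_search(feats, "svm", NULL), "empty")
})

test_that("margin classifier attains perfect LOOCV accuracy when separable", {
  feats <- make_toy_features(n = 20, separation = 8, seed = 4)
  res <- loocv_grid_search(feats, "svm",
                           data.frame(kernel = "radial", cost = 10,
                                      gamma = NA_real_,
                                      stringsAsFactors = FALSE),
                           seed = 1)
  expect_equal(res$cv_accuracy, 1.0)
})

test_that("ensemble probability is a convex combination of member votes", {
  feats <- make_toy_features(n = 30, separation = 2, seed = 6)
  ens <- train_ensemble(feats, grids = default_grids(compact = TRUE),
                        seed = 2)
  expect_equal(sum(ens$weights), 1)
  expect_true(all(ens$weights >= 0))

  newdata <- make_toy_features(n = 12, separation = 2, seed = 16)
  pred <- predict_soft_vote(ens, newdata)
  X <- as.matrix(newdata[, ens$feature_cols])
  Xs <- sweep(sweep(X, 2, ens$scaling$mean), 2, ens$scaling$sd, "/")
  member_p <- sapply(names(ens$members), function(m) {
    Xm <- if (trajex:::scale_sensitive(m)) Xs else X
    trajex:::predict_learner(ens$members[[m]]$fit, Xm, type = "prob")
  })
  expect_true(all(pred$prob >= apply(member_p, 1, min) - 1e-12))
  expect_true(all(pred$prob <= apply(member_p, 1, max) + 1e-12))
  expect_equal(pred$prob, rowMeans(member_p), tolerance = 1e-12)

  # degenerate weights (1, 0, ...): vote equals the first member
  ens1 <- ens
  ens1$weights <- setNames(c(1, rep(0, length(ens$weights) - 1)),
                           names(ens$weights))
  pred1 <- predict_soft_vote(ens1, newdata)
  expect_equal(pred1$prob, unname(member_p[, 1]), tolerance = 1e-12)

  expect_error(predict_soft_vote(ens, newdata[, c("subject_id", "x1")]),
               "missing feature")
})

test_that("a probability tie at exactly 0.5 is labelled class 1", {
  # k = 2 kNN with one neighbour per class at equal distance
  train <- data.frame(subject_id = c("a", "b"), label = c(0L, 1L),
                      x1 = c(-1, 1), stringsAsFactors = FALSE)
  attr(train, "feature_cols") <- "x1"
  fit <- trajex:::fit_learner("knn", list(k = 2, metric = "euclidean"),
                              as.matrix(train["x1"]), train$label)
  ens <- structure(list(
    members = list(knn = list(fit = fit)),
    weights = c(knn = 1),
    scaling = list(mean = c(x1 = 0), sd = c(x1 = 1)),
    feature_cols = "x1"), class = "ensemble_model")
  pred <- predict_soft_vote(ens, data.frame(x1 = 0))
  expect_equal(pred$prob, 0.5)
  expect_equal(pred$label, 1L)
})

test_that("ensemble training is deterministic given the seed", {
  feats <- make_toy_features(n = 24, separation = 1.5, seed = 10)
  e1 <- train_ensemble(feats, grids = default_grids(compact = TRUE), seed = 5)
  e2 <- train_ensemble(feats, grids = default_grids(compact = TRUE), seed = 5)
  newdata <- make_toy_features(n = 10, separation = 1.5, seed = 11)
  expect_identical(predict_soft_vote(e1, newdata),
                   predict_soft_vote(e2, newdata))
})
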