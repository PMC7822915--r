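#' Censor converter visits at conversion
#'
#' Removes, for every converter (cMCI, cAD), all visits — in both the
#' cognitive and MRI streams — at or after the first visit carrying the
#' converted diagnosis. No downstream feature may use information from the
#' point of conversion onward, since the classifier's task is to predict
#' future conversion. Stable subjects (HC, sMCI) are returned unchanged.
#'
#' A converter whose censored series retains fewer than two visits in a
#' modality cannot yield an endpoint slope (d-slope) there; feature building
#' records the value as missing and imputes the training median (see
#' \code{\link{build_feature_table}}).
#'
#' @param cohort Long-format cohort data.frame (one or many subjects).
#' @return The censored cohort.
#' @export
censor_post_conversion <- function(cohort) {
  keep <- rep(TRUE, nrow(cohort))
  for (id in unique(cohort$subject_id)) {
    idx <- which(cohort$subject_id == id)
    conv <- conversion_age(cohort[idx, ])
    if (!is.na(conv)) keep[idx[cohort$age[idx] >= conv]] <- FALSE
  }
  out <- cohort[keep, ]
  rownames(out) <- NULL
  out
}

#' Normalize a regional volume by intracranial volume
#'
#' Dividing a regional brain volume (mm^3) by the estimated total
#' intracranial volume (eTIV, mm^3) removes head-size differences (and much
#' of the sex difference) before trajectory modelling. Thickness measures
#' and test scores are not normalized.
#'
#' @param value Regional volume(s), mm^3.
#' @param etiv Estimated total intracranial volume(s), mm^3; must be > 0.
#' @return Dimensionless ratio(s).
#' @examples
#' normalize_volume(4000, 1.6e6)  # 0.0025
#' @export
normalize_volume <- function(value, etiv) {
  if (any(is.na(etiv)) || any(etiv <= 0)) {
    stop("etiv must be present and > 0", call. = FALSE)
  }
  value / etiv
}

# Extract one subject-measure series (age-sorted), applying eTIV
# normalization where the measure spec requires it.
measure_series <- function(rows, spec) {
  d <- rows[rows$measure == spec$measure, , drop = FALSE]
  if (nrow(d) == 0L) return(d)
  d <- d[order(d$age), , drop = FALSE]
  if (isTRUE(spec$normalize_by_etiv)) {
    d$value <- normalize_volume(d$value, d$etiv)
  }
  d
}

#' Construct a trajectory model object
#'
#' Container for a per-measure mixed-effects trajectory model: fixed effects
#' for the population age curve, the between-subject covariance of the
#' random intercept/slope (and quadratic term for order-2 measures),
#' the residual variance, and — when produced by
#' \code{\link{fit_trajectory_model}} — the empirical-Bayes random effects of
#' the training subjects. Ages are centred at \code{age_center} (years)
#' before entering the model; the centring constant travels with the model
#' so features for new subjects are computed on the same scale.
#'
#' @param measure Measure name.
#' @param order Polynomial order, 1 or 2.
#' @param beta Fixed effects: \code{c(b0, b1)} or \code{c(b0, b1, b2)} on the
#'   centred-age scale.
#' @param D Random-effect covariance matrix (2x2 or 3x3), symmetric PSD.
#' @param sigma2 Residual variance, >= 0.
#' @param age_center Centring constant, years.
#' @param normalize_by_etiv Whether the model was fitted on eTIV-normalized
#'   values.
#' @param ranef Optional data.frame of training-subject random effects
#'   (\code{subject_id}, \code{b0}, \code{b1}[, \code{b2}]).
#' @param n_train Number of training subjects used in the fit.
#' @return An object of class \code{trajectory_model}.
#' @export
trajectory_model <- function(measure, order, beta, D, sigma2, age_center,
                             normalize_by_etiv = FALSE, ranef = NULL,
                             n_train = NA_integer_) {
  q <- order + 1L
  stopifnot(length(beta) == q, nrow(D) == q, ncol(D) == q, sigma2 >= 0)
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric", call. = FALSE)
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("D must be positive semi-definite", call. = FALSE)
  }
  structure(
    list(measure = measure, order = as.integer(order),
         beta = unname(beta), D = unname(as.matrix(D)), sigma2 = sigma2,
         age_center = age_center, normalize_by_etiv = normalize_by_etiv,
         ranef = ranef, n_train = n_train),
    class = "trajectory_model"
  )
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("Trajectory model for", x$measure,
      sprintf("(order %d, age centred at %.2f)\n", x$order, x$age_center))
  cat("  fixed effects:", paste(sprintf("%.6g", x$beta), collapse = ", "), "\n")
  cat(sprintf("  residual sd: %.6g; %d training subjects\n",
              sqrt(x$sigma2), x$n_train))
  invisible(x)
}

#' Fit a mixed-effects trajectory model for one measure
#'
#' Fits, by REML via \code{lme4::lmer}, the model
#' \deqn{M_{ij} = \beta_0 + \beta_1 Age_{ij} + b_{0i} + b_{1i} Age_{ij} + \epsilon_{ij}}
#' (plus \eqn{\beta_2 Age^2_{ij} + b_{2i} Age^2_{ij}} for order-2 measures,
#' i.e. the lateral ventricles), where age is the only predictor. Ages are
#' centred at the training-sample mean age for the measure (the quadratic
#' term is numerically ill-conditioned around age ~75 otherwise); the
#' centring constant is stored in the returned model. Volumes are
#' eTIV-normalized before fitting when the measure spec requires it.
#'
#' Only training subjects may be present in \code{cohort}: every subject in
#' the data influences the fixed effects and variance components, so
#' held-out subjects must be excluded upstream and their random effects
#' obtained afterwards with \code{\link{predict_random_effects}}.
#'
#' @param cohort Long-format cohort rows for the training subjects (already
#'   censored at conversion).
#' @param spec A single row of \code{\link{measure_specs}} (or a measure
#'   name).
#' @param age_center Optional centring constant; defaults to the mean age of
#'   the observations used.
#' @return A \code{\link{trajectory_model}} with training-subject random
#'   effects attached.
#' @export
fit_trajectory_model <- function(cohort, spec, age_center = NULL) {
  if (is.character(spec)) spec <- measure_spec(spec)
  d <- cohort[cohort$measure == spec$measure, , drop = FALSE]
  if (isTRUE(spec$normalize_by_etiv)) {
    d$value <- normalize_volume(d$value, d$etiv)
  }
  n_per <- table(d$subject_id)
  if (sum(n_per >= 2) < 2) {
    stop("need >= 2 training subjects with >= 2 visits for ", spec$measure,
         call. = FALSE)
  }
  if (is.null(age_center)) age_center <- mean(d$age)
  d$age_c <- d$age - age_center
  form <- if (spec$polynomial_order == 2L) {
    value ~ age_c + I(age_c^2) + (age_c + I(age_c^2) | subject_id)
  } else {
    value ~ age_c + (age_c | subject_id)
  }
  fit <- tryCatch(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    error = function(e) stop("mixed model for ", spec$measure,
                             " failed to converge: ", conditionMessage(e),
                             call. = FALSE)
  )
  beta <- unname(lme4::fixef(fit))
  vc <- lme4::VarCorr(fit)$subject_id
  D <- matrix(as.numeric(vc), nrow(vc), ncol(vc))
  D <- (D + t(D)) / 2
  sigma2 <- stats::sigma(fit)^2
  re <- lme4::ranef(fit)$subject_id
  ranef_df <- data.frame(subject_id = rownames(re),
                         setNames(as.data.frame(re),
                                  c("b0", "b1", "b2")[seq_len(ncol(re))]),
                         stringsAsFactors = FALSE)
  rownames(ranef_df) <- NULL
  trajectory_model(
    measure = spec$measure, order = spec$polynomial_order, beta = beta,
    D = D, sigma2 = sigma2, age_center = age_center,
    normalize_by_etiv = isTRUE(spec$normalize_by_etiv), ranef = ranef_df,
    n_train = length(unique(d$subject_id))
  )
}

# Design matrix on the centred-age scale: columns 1, age_c [, age_c^2].
trajectory_design <- function(model, ages) {
  a <- ages - model$age_center
  if (model$order == 2L) cbind(1, a, a^2) else cbind(1, a)
}

#' Predict random effects for a (possibly held-out) subject
#'
#' Computes the empirical-Bayes best linear unbiased predictor (BLUP) of a
#' subject's random-effect vector conditional on the train-fitted fixed
#' effects, random-effect covariance \eqn{D}, and residual variance:
#' \deqn{\hat b_i = D Z_i' V_i^{-1} (y_i - X_i \beta), \quad
#'       V_i = Z_i D Z_i' + \sigma^2 I.}
#' This is how feature values are obtained for held-out subjects without
#' refitting — the subject's data never touch the model parameters — and,
#' applied to a training subject, it reproduces the random effects stored by
#' the fitter to numerical tolerance.
#'
#' @param model A \code{\link{trajectory_model}}.
#' @param visits Data.frame with columns \code{age} and \code{value} (raw
#'   scale; plus \code{etiv} if the model is eTIV-normalized) for one
#'   subject; at least one row.
#' @return Numeric vector \code{c(b0, b1)} or \code{c(b0, b1, b2)}.
#' @export
predict_random_effects <- function(model, visits) {
  if (nrow(visits) == 0L) stop("subject has no visits", call. = FALSE)
  y <- visits$value
  if (isTRUE(model$normalize_by_etiv)) {
    y <- normalize_volume(y, visits$etiv)
  }
  Z <- trajectory_design(model, visits$age)
  resid <- y - drop(Z %*% model$beta)
  V <- Z %*% model$D %*% t(Z) + model$sigma2 * diag(nrow(Z))
  drop(model$D %*% t(Z) %*% solve(V, resid))
}

#' Deviation of the first observation from the cohort curve
#'
#' The \emph{dev} feature: the subject's first (earliest-age) measurement
#' minus the fixed-effect prediction at that age,
#' \eqn{M_{i1} - (\beta_0 + \beta_1 Age_{i1})}, including the
#' \eqn{\beta_2 Age_{i1}^2} term for order-2 measures. It captures where the
#' subject entered the study relative to the cohort-average trajectory.
#'
#' @inheritParams predict_random_effects
#' @return Scalar, in measure units.
#' @export
compute_dev <- function(model, visits) {
  if (nrow(visits) == 0L) stop("subject has no visits", call. = FALSE)
  first <- which.min(visits$age)
  y1 <- visits$value[first]
  if (isTRUE(model$normalize_by_etiv)) {
    y1 <- normalize_volume(y1, visits$etiv[first])
  }
  X1 <- trajectory_design(model, visits$age[first])
  unname(y1 - drop(X1 %*% model$beta))
}

#' Endpoint rate of change (d-slope)
#'
#' The difference between the last and first measurements divided by the
#' time between them:
#' \deqn{\mathrm{d\mbox{-}slope}_i = (M_{i n_i} - M_{i0}) / (Age_{i n_i} - Age_{i0}).}
#' Unlike the model-based random slope it depends only on the subject's own
#' endpoints, so identical total change over short and long participation
#' spans yields different values. Visits are sorted by age internally.
#'
#' @param visits Data.frame with columns \code{age} and \code{value}; at
#'   least two rows with distinct ages.
#' @return Scalar, measure units per year.
#' @examples
#' compute_d_slope(data.frame(age = c(70, 72), value = c(10, 8)))  # -1
#' @export
compute_d_slope <- function(visits) {
  if (nrow(visits) < 2L) {
    stop("d-slope requires at least two visits", call. = FALSE)
  }
  o <- order(visits$age)
  a1 <- visits$age[o[1]]; a2 <- visits$age[o[length(o)]]
  if (a2 - a1 <= 0) {
    stop("d-slope requires distinct first/last ages", call. = FALSE)
  }
  (visits$value[o[length(o)]] - visits$value[o[1]]) / (a2 - a1)
}

#' Serialize / restore a trajectory model
#'
#' Plain-JSON persistence of the fixed effects, covariance, residual
#' variance, centring constant and training random effects, so fitted
#' trajectories can be reused across sessions.
#'
#' @param model A \code{\link{trajectory_model}}.
#' @param path JSON file path.
#' @return \code{write_trajectory_model}: \code{path}, invisibly;
#'   \code{read_trajectory_model}: the model.
#' @export
write_trajectory_model <- function(model, path) {
  payload <- list(
    measure = model$measure, order = model$order, beta = model$beta,
    D = model$D, sigma2 = model$sigma2, age_center = model$age_center,
    normalize_by_etiv = model$normalize_by_etiv, n_train = model$n_train,
    ranef = model$ranef
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_trajectory_model
#' @export
read_trajectory_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranef <- if (is.null(p$ranef) || length(p$ranef) == 0) NULL else
    as.data.frame(p$ranef, stringsAsFactors = FALSE)
  trajectory_model(
    measure = p$measure, order = p$order, beta = p$beta,
    D = matrix(unlist(p$D), p$order + 1L, p$order + 1L),
    sigma2 = p$sigma2, age_center = p$age_center,
    normalize_by_etiv = isTRUE(p$normalize_by_etiv), ranef = ranef,
    n_train = p$n_train
  )
}
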