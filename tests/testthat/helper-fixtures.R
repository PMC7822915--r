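# Fixtures are built in code at test time; nothing is read from disk.

# Long-format single-measure cohort with known subject-level truth:
# value_ij = beta0 + beta1 * age_ij + b0_i + b1_i * age_ij + eps_ij.
# Returns the data plus the true random effects as attributes.
make_linear_cohort <- function(n_subjects, beta0, beta1,
                               int_sd = 2, slope_sd = 0.2, resid_sd = 1,
                               ages = 70 + 0:5, measure = "adas13",
                               seed = 1) {
  set.seed(seed)
  b0 <- rnorm(n_subjects, 0, int_sd)
  b1 <- rnorm(n_subjects, 0, slope_sd)
  rows <- lapply(seq_len(n_subjects), function(i) {
    data.frame(
      subject_id = sprintf("S%03d", i), sex = "f", education = 16,
      subgroup = "sMCI", modality = "cognitive",
      visit_index = seq_along(ages), age = ages, diagnosis = "MCI",
      measure = measure,
      value = beta0 + beta1 * ages + b0[i] + b1[i] * ages +
        rnorm(length(ages), 0, resid_sd),
      etiv = NA_real_, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "true_b0") <- b0
  attr(out, "true_b1") <- b1
  out
}

# Small two-feature toy classification table: x1 carries the class signal,
# x2 is pure noise.
make_toy_features <- function(n = 20, separation = 3, seed = 1) {
  set.seed(seed)
  label <- rep(0:1, length.out = n)
  out <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    label = label,
    x1 = rnorm(n) + separation * label,
    x2 = rnorm(n),
    stringsAsFactors = FALSE
  )
  attr(out, "feature_cols") <- c("x1", "x2")
  out
}

# Reduced-size cohort config for fast end-to-end tests.
tiny_config <- function(n = 16, seed = 1, ...) {
  default_config(n_per_group = c(HC = n, cMCI = n, sMCI = n, cAD = n),
                 seed = seed, ...)
}

# Fast two-family grids for pipeline plumbing tests (deterministic members).
fast_grids <- function() {
  list(
    logistic = data.frame(penalty = "l2", lambda = 0.1,
                          stringsAsFactors = FALSE),
    knn = data.frame(k = 5, metric = "euclidean", stringsAsFactors = FALSE)
  )
}
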