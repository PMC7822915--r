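test_that("censoring removes visits from conversion onward, both modalities", {
  co <- generate_cohort(tiny_config(n = 10, seed = 31))
  ss <- subject_summary(co)
  cen <- censor_post_conversion(co)

  # stable subjects untouched
  stable_ids <- ss$subject_id[ss$subgroup %in% c("HC", "sMCI")]
  expect_identical(cen[cen$subject_id %in% stable_ids, ],
                   co[co$subject_id %in% stable_ids, ],
                   ignore_attr = TRUE)

  # converters keep only strictly pre-conversion visits
  for (id in ss$subject_id[!is.na(ss$conversion_age)]) {
    conv <- ss$conversion_age[ss$subject_id == id]
    kept <- cen[cen$subject_id == id, ]
    expect_true(all(kept$age < conv))
    expect_true(all(kept$diagnosis ==
                      subgroup_diagnoses(kept$subgroup[1])$pre))
    expect_gt(nrow(kept), 0)
  }
})

test_that("volume normalization is value/etiv with a positive-etiv guard", {
  expect_equal(normalize_volume(1.6e6, 1.6e6), 1.0)
  expect_equal(normalize_volume(4000, 1.6e6), 0.0025)
  expect_error(normalize_volume(4000, 0), "etiv")
  expect_error(normalize_volume(4000, NA), "etiv")
})

test_that("mixed model recovers fixed effects and is exact on noiseless data", {
  # noiseless common line: M = 10 - 0.1 * Age for every subject
  ages <- 70 + 0:4
  rows <- lapply(1:12, function(i) {
    data.frame(subject_id = sprintf("N%02d", i), age = ages,
               measure = "adas13", value = 10 - 0.1 * ages,
               etiv = NA_real_, stringsAsFactors = FALSE)
  })
  noiseless <- do.call(rbind, rows)
  m <- suppressWarnings(
    fit_trajectory_model(noiseless, "adas13", age_center = 0))
  expect_equal(m$beta[1], 10, tolerance = 1e-4)
  expect_equal(m$beta[2], -0.1, tolerance = 1e-4)
  expect_lt(max(abs(as.matrix(m$ranef[, c("b0", "b1")]))), 1e-4)
  expect_lt(m$sigma2, 1e-6)

  # stochastic recovery at moderate n
  co <- make_linear_cohort(60, beta0 = 50, beta1 = -0.5, int_sd = 2,
                           slope_sd = 0.2, resid_sd = 1, seed = 42)
  m2 <- fit_trajectory_model(co, "adas13")
  slope <- m2$beta[2]
  expect_lt(abs(slope - (-0.5)), 0.1)
})

test_that("BLUP is zero for on-curve subjects and shrinks toward zero", {
  m <- trajectory_model("adas13", 1, beta = c(5, 0.3),
                        D = diag(c(4, 0.04)), sigma2 = 1, age_center = 0)
  on_curve <- data.frame(age = c(70, 72, 74), value = 5 + 0.3 * c(70, 72, 74))
  expect_equal(predict_random_effects(m, on_curve), c(0, 0),
               tolerance = 1e-12)

  # random-intercept-only model: |BLUP| below |mean residual| (shrinkage)
  m0 <- trajectory_model("adas13", 1, beta = c(5, 0),
                         D = diag(c(4, 0)), sigma2 = 2, age_center = 0)
  set.seed(8)
  for (rep in 1:20) {
    v <- data.frame(age = 70 + 0:2, value = 5 + rnorm(3, 2, 1))
    b <- predict_random_effects(m0, v)
    expect_lt(abs(b[1]), abs(mean(v$value - 5)))
    expect_equal(b[2], 0)
  }
})

test_that("hand-assembled BLUP reproduces lme4's stored random effects", {
  co <- make_linear_cohort(40, beta0 = 30, beta1 = -0.4, int_sd = 3,
                           slope_sd = 0.3, resid_sd = 1, seed = 7)
  m <- fit_trajectory_model(co, "adas13")
  for (id in sample(unique(co$subject_id), 10)) {
    visits <- co[co$subject_id == id, c("age", "value", "etiv")]
    b <- predict_random_effects(m, visits)
    stored <- as.numeric(m$ranef[m$ranef$subject_id == id, c("b0", "b1")])
    expect_equal(b, stored, tolerance = 1e-6)
  }
})

test_that("dev and d-slope follow their defining arithmetic", {
  m <- trajectory_model("adas13", 1, beta = c(2, 0.5),
                        D = diag(c(1, 0.01)), sigma2 = 1, age_center = 0)
  expect_equal(compute_dev(m, data.frame(age = 70, value = 40)), 3)
  expect_equal(compute_dev(m, data.frame(age = 70, value = 37)), 0)

  mq <- trajectory_model("ventricle_lh", 2, beta = c(1, 0, 0.01),
                         D = diag(c(1, 0.01, 1e-4)), sigma2 = 1,
                         age_center = 0)
  expect_equal(compute_dev(mq, data.frame(age = 10, value = 3)), 1)

  expect_equal(compute_d_slope(data.frame(age = c(70, 72),
                                          value = c(10, 8))), -1)
  expect_equal(compute_d_slope(data.frame(age = c(70, 71, 75),
                                          value = c(4, 9, 4))), 0)
  expect_error(compute_d_slope(data.frame(age = 70, value = 4)),
               "two visits")
  expect_error(compute_d_slope(data.frame(age = c(70, 70),
                                          value = c(1, 2))), "distinct")
})

test_that("dev and d-slope are invariant to visit row order", {
  m <- trajectory_model("adas13", 1, beta = c(2, 0.5),
                        D = diag(c(1, 0.01)), sigma2 = 1, age_center = 0)
  v <- data.frame(age = c(74, 70, 72), value = c(6, 11, 2))
  shuffled <- v[c(2, 3, 1), ]
  expect_equal(compute_dev(m, v), compute_dev(m, shuffled))
  expect_equal(compute_d_slope(v), compute_d_slope(shuffled))
})

test_that("feature table has the documented shape and censoring semantics", {
  co <- generate_cohort(tiny_config(n = 12, seed = 61))
  ss <- subject_summary(co)
  cen <- censor_post_conversion(co)
  d <- cen[cen$subgroup %in% c("sMCI", "cAD"), ]

  models_cog <- fit_trajectory_models(d, "cog")
  ft_cog <- build_feature_table(d, models_cog, "smci-cad", "cog")
  expect_length(attr(ft_cog, "feature_cols"), 11)  # 3x3 + sex + current_age
  expect_false(any(grepl("hippo|ventricle|entorhinal",
                         names(ft_cog))))

  models_all <- suppressWarnings(fit_trajectory_models(d, "cog+mri"))
  ft <- build_feature_table(d, models_all, "smci-cad", "cog+mri")
  expect_length(attr(ft, "feature_cols"), 31)  # 9x3 + 2 quad + sex + age
  expect_setequal(grep("_quad$", names(ft), value = TRUE),
                  c("ventricle_lh_quad", "ventricle_rh_quad"))
  expect_setequal(ft$label, c(0, 1))
  expect_true(all(ft$label[grepl("^cAD", ft$subject_id)] == 1))

  # converters: current_age strictly before conversion
  conv <- ss[!is.na(ss$conversion_age) & ss$subgroup == "cAD", ]
  for (id in conv$subject_id) {
    if (!id %in% ft$subject_id) next
    expect_lt(ft$current_age[ft$subject_id == id],
              conv$conversion_age[conv$subject_id == id])
  }
  expect_false(anyNA(ft[, attr(ft, "feature_cols")]))
})

test_that("trajectory models survive JSON round-trips", {
  co <- make_linear_cohort(20, beta0 = 12, beta1 = -0.2, seed = 3)
  m <- fit_trajectory_model(co, "adas13")
  path <- withr::local_tempfile(fileext = ".json")
  write_trajectory_model(m, path)
  back <- read_trajectory_model(path)
  expect_equal(back$beta, m$beta)
  expect_equal(back$D, m$D)
  expect_equal(back$sigma2, m$sigma2)
  expect_equal(back$age_center, m$age_center)
  v <- co[co$subject_id == "S001", c("age", "value", "etiv")]
  expect_equal(predict_random_effects(back, v),
               predict_random_effects(m, v))
})
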