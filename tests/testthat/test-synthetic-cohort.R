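test_that("cohort generation is deterministic under seed and seeds differ", {
  cfg <- tiny_config(n = 6, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- tiny_config(n = 6, seed = 8)
  expect_false(identical(generate_cohort(cfg2), a))
})

test_that("default configuration carries the emulated cohort structure", {
  cfg <- default_config()
  vs <- cfg$visit_schedule
  expect_equal(vs$mean_count[vs$subgroup == "sMCI" & vs$modality == "mri"],
               5.1)
  expect_equal(vs$mean_interval[vs$subgroup == "cAD" & vs$modality == "mri"],
               0.53)
  tr <- cfg$trajectory
  expect_equal(tr$intercept_mean[tr$subgroup == "cAD" &
                                   tr$measure == "ravlt_im"], 29.4)
  expect_equal(tr$intercept_mean[tr$subgroup == "cAD" &
                                   tr$measure == "adas13"], 21.8)
  expect_equal(unname(cfg$n_per_group[c("HC", "cMCI", "sMCI", "cAD")]),
               c(134L, 134L, 333L, 333L))
  # converter decline steeper than the matched stable group, every measure
  specs <- measure_specs()
  for (m in specs$measure) {
    dirn <- if (specs$impairment_direction[specs$measure == m] ==
                  "higher-is-worse") 1 else -1
    sl <- function(g) tr$slope_mean[tr$subgroup == g & tr$measure == m]
    expect_gt(dirn * sl("cAD"), dirn * sl("sMCI"))
    expect_gt(dirn * sl("cMCI"), dirn * sl("HC"))
  }
  # exactly one spec per measure, quadratic only on ventricles
  expect_false(any(duplicated(specs$measure)))
  expect_setequal(specs$measure[specs$polynomial_order == 2L],
                  c("ventricle_lh", "ventricle_rh"))
  expect_true(all(!specs$normalize_by_etiv[specs$modality == "cognitive"]))
})

test_that("zero-variance config puts observations exactly on the mean trajectory", {
  cfg <- tiny_config(n = 4, seed = 3)
  tr <- cfg$trajectory
  tr$intercept_sd <- 0; tr$slope_sd <- 0; tr$quad_sd <- 0; tr$resid_sd <- 0
  cfg$trajectory <- tr
  co <- generate_cohort(cfg)
  ref <- cfg$baseline_age$mean
  for (i in sample(nrow(co), 200)) {
    p <- tr[tr$subgroup == co$subgroup[i] & tr$measure == co$measure[i], ]
    dt <- co$age[i] - ref
    expected <- p$intercept_mean + p$slope_mean * dt + p$quad_mean * dt^2
    clip <- cfg$clip_ranges[[co$measure[i]]]
    expected <- min(max(expected, clip[1]), clip[2])
    expect_equal(co$value[i], expected, tolerance = 1e-12)
  }
})

test_that("baseline group means converge to the calibrated values", {
  cfg <- default_config(n_per_group = c(HC = 500, cMCI = 500,
                                        sMCI = 500, cAD = 500), seed = 99)
  co <- generate_cohort(cfg)
  base <- co[co$modality == "cognitive" & co$visit_index == 1, ]
  for (case in list(c("cAD", "adas13"), c("cAD", "ravlt_im"),
                    c("HC", "ravlt_im"), c("sMCI", "ravlt_pf"))) {
    v <- base$value[base$subgroup == case[1] & base$measure == case[2]]
    target <- cfg$trajectory$intercept_mean[
      cfg$trajectory$subgroup == case[1] &
        cfg$trajectory$measure == case[2]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 3 * se)
  }
})

test_that("diagnosis sequences are consistent with the subgroup labels", {
  co <- generate_cohort(tiny_config(n = 12, seed = 5))
  ss <- subject_summary(co)
  expect_true(all(is.na(ss$conversion_age[ss$subgroup %in% c("HC", "sMCI")])))
  expect_true(all(!is.na(ss$conversion_age[ss$subgroup %in%
                                             c("cMCI", "cAD")])))
  for (id in ss$subject_id) {
    d <- co[co$subject_id == id, ]
    g <- d$subgroup[1]
    rule <- subgroup_diagnoses(g)
    if (!rule$converter) {
      expect_true(all(d$diagnosis == rule$pre))
    } else {
      conv <- ss$conversion_age[ss$subject_id == id]
      expect_true(all(d$diagnosis[d$age < conv] == rule$pre))
      expect_true(all(d$diagnosis[d$age >= conv] == rule$post))
      # at least one strictly pre-conversion visit in each modality
      for (mod in c("cognitive", "mri")) {
        expect_gt(sum(d$age[d$modality == mod] < conv), 0)
      }
    }
  }
})

test_that("cohort-level ventricle trajectories are convex in age", {
  co <- generate_cohort(default_config(
    n_per_group = c(HC = 60, cMCI = 60, sMCI = 60, cAD = 60), seed = 21))
  v <- co[co$measure == "ventricle_lh", ]
  fit <- lm(value ~ age + I(age^2), data = v)
  expect_gt(coef(fit)[["I(age^2)"]], 0)
})

test_that("cohort CSV round-trips through write and read", {
  co <- generate_cohort(tiny_config(n = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$age, co$age, tolerance = 1e-4)
  expect_equal(back$value, co$value, tolerance = 1e-8)
  expect_identical(back$subject_id, co$subject_id)
  expect_identical(back$diagnosis, co$diagnosis)
  expect_identical(is.na(back$etiv), is.na(co$etiv))
  # a second write of the re-read cohort is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed cohort files are rejected with informative errors", {
  co <- generate_cohort(tiny_config(n = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- co
  i <- which(bad$subject_id == bad$subject_id[1] &
               bad$modality == "cognitive" & bad$measure == "adas13")
  bad$age[i[2]] <- bad$age[i[1]] - 5   # age goes backwards at visit 2
  write_cohort(bad, path)
  expect_error(read_cohort(path), "age decreases.*HC_0001")

  writeLines(paste(c("subject_id,sex,education,subgroup,modality",
                     "visit_index,age,diagnosis,measure,value,etiv"),
                   collapse = ","), path)
  expect_error(read_cohort(path), "no records")

  bad2 <- co
  bad2$diagnosis[5] <- "DEM"
  write_cohort(bad2, path)
  expect_error(read_cohort(path), "unknown diagnosis.*5")
})

test_that("flat-YAML config files round-trip", {
  cfg <- tiny_config(n = 9, seed = 13)
  cfg$trajectory$slope_mean[3] <- -1.25
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$n_per_group, cfg$n_per_group)
  expect_equal(back$trajectory, cfg$trajectory)
  expect_equal(back$visit_schedule, cfg$visit_schedule)
  expect_equal(back$clip_ranges, cfg$clip_ranges)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})

test_that("invalid configurations are rejected", {
  cfg <- tiny_config(n = 4)
  cfg$n_per_group[["HC"]] <- 0L
  expect_error(validate_config(cfg), "positive")
  cfg <- tiny_config(n = 4)
  cfg$visit_schedule$mean_count[1] <- 1.5
  expect_error(validate_config(cfg), ">= 2")
  cfg <- tiny_config(n = 4)
  cfg$trajectory$slope_sd[1] <- -1
  expect_error(validate_config(cfg), "SD")
})
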