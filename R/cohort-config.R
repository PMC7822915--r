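#' Default synthetic-cohort configuration
#'
#' Builds the configuration used by \code{\link{generate_cohort}}. Group
#' sizes, visit counts and inter-visit intervals, and the cognitive-test
#' means/SDs reproduce the published ADNI-derived cohort summaries this
#' package emulates (134 HC, 134 cMCI, 333 sMCI, 333 cAD; e.g. sMCI subjects
#' average 5.1 MRI scans 0.48 years apart and 6.0 cognitive tests 0.63 years
#' apart). Cognitive intercepts are calibrated to the training-set female
#' column of the source summaries; MRI volume and thickness scales are
#' typical FreeSurfer values (hippocampus ~3.0-3.7e3 mm3 per side, lateral
#' ventricle ~2-3e4 mm3, entorhinal thickness ~3 mm, eTIV ~1.5e6 mm3) with
#' annual decline steeper in converter groups. Lateral ventricles carry a
#' positive quadratic term (accelerating expansion); all other measures are
#' linear in age.
#'
#' Trajectories are parameterized relative to the reference age
#' \code{baseline_age$mean}: a subject's expected value at age \eqn{t} is
#' \code{intercept + slope * (t - ref) + quad * (t - ref)^2}, with
#' subject-level intercept/slope/quad drawn from the configured
#' between-subject distributions. The intercept mean is therefore also the
#' expected value at the mean baseline age.
#'
#' @param n_per_group Named integer vector of subjects per subgroup
#'   (names \code{HC}, \code{cMCI}, \code{sMCI}, \code{cAD}).
#' @param seed Integer seed; \code{generate_cohort} is deterministic given
#'   the config (including this seed).
#' @param mri_dominant_hc_cmci If \code{TRUE}, return an alternative
#'   calibration in which HC and cMCI have identical cognitive trajectories
#'   but clearly separated MRI decline rates. This emulates the regime where
#'   structural brain change precedes measurable cognitive change, so MRI
#'   features carry the class signal for HC vs cMCI.
#' @param cross_measure_rho Correlation (0..1) between a subject's latent
#'   severity and their per-measure random effects: 0 (default) draws
#'   subject effects independently across measures; larger values make
#'   decline co-occur across measures within subject.
#' @return A list of class \code{cohort_config}; see the fields in the
#'   source or \code{str(default_config())}.
#' @seealso \code{\link{generate_cohort}}, \code{\link{write_config}}
#' @examples
#' cfg <- default_config(n_per_group = c(HC = 10, cMCI = 10, sMCI = 10, cAD = 10))
#' cohort <- generate_cohort(cfg)
#' @export
default_config <- function(n_per_group = c(HC = 134L, cMCI = 134L,
                                           sMCI = 333L, cAD = 333L),
                           seed = 1L,
                           mri_dominant_hc_cmci = FALSE,
                           cross_measure_rho = 0) {
  # Table-calibrated visit structure: mean number of visits and mean
  # inter-visit interval (years), per subgroup and modality.
  visit_schedule <- data.frame(
    subgroup      = rep(subgroup_levels(), each = 2),
    modality      = rep(c("mri", "cognitive"), 4),
    mean_count    = c(4.8, 6.0,  5.5, 7.0,  5.1, 6.0,  5.6, 6.5),
    mean_interval = c(0.58, 0.78, 0.62, 0.80, 0.48, 0.63, 0.53, 0.62),
    stringsAsFactors = FALSE
  )

  tp <- function(measure, intercepts, int_sd, slopes, slope_sd, resid_sd,
                 quads = rep(0, 4), quad_sd = rep(0, 4)) {
    data.frame(
      subgroup = subgroup_levels(), measure = measure,
      intercept_mean = intercepts, intercept_sd = int_sd,
      slope_mean = slopes, slope_sd = slope_sd,
      quad_mean = quads, quad_sd = quad_sd,
      resid_sd = resid_sd, stringsAsFactors = FALSE
    )
  }

  trajectory <- rbind(
    # cognitive tests: intercepts/SDs from the emulated cohort summaries
    tp("ravlt_im", c(47.4, 47.3, 38.7, 29.4), c(10, 10, 11, 9),
       c(-0.2, -0.8, -0.8, -2.2), c(0.4, 0.5, 0.5, 0.8), 4.0),
    tp("ravlt_pf", c(30.8, 33.1, 54.7, 81.8), c(27, 26, 33, 28),
       c(0.8, 2.0, 2.0, 5.0), c(1.0, 1.5, 1.5, 2.0), 12.0),
    tp("adas13",   c(8.2, 8.6, 14.3, 21.8), c(4, 4, 7, 7),
       c(0.15, 0.6, 0.8, 2.4), c(0.25, 0.4, 0.4, 0.8), 2.5),
    # MRI volumes in mm3, thickness in mm (raw scale; eTIV normalization
    # happens at feature time)
    tp("hippo_lh", c(3700, 3550, 3350, 3050), c(450, 450, 450, 450),
       c(-15, -35, -40, -75), c(10, 15, 15, 25), 70),
    tp("hippo_rh", c(3750, 3600, 3400, 3100), c(450, 450, 450, 450),
       c(-15, -35, -40, -75), c(10, 15, 15, 25), 70),
    tp("entorhinal_lh", c(3.35, 3.25, 3.15, 2.95), c(0.30, 0.30, 0.30, 0.30),
       c(-0.008, -0.020, -0.025, -0.050),
       c(0.008, 0.012, 0.012, 0.020), 0.07),
    tp("entorhinal_rh", c(3.38, 3.28, 3.18, 2.98), c(0.30, 0.30, 0.30, 0.30),
       c(-0.008, -0.020, -0.025, -0.050),
       c(0.008, 0.012, 0.012, 0.020), 0.07),
    tp("ventricle_lh", c(21000, 23000, 26000, 31000), rep(8000, 4),
       c(350, 550, 700, 1100), c(200, 250, 300, 400), 600,
       quads = c(12, 18, 22, 35), quad_sd = rep(8, 4)),
    tp("ventricle_rh", c(20500, 22500, 25500, 30500), rep(8000, 4),
       c(350, 550, 700, 1100), c(200, 250, 300, 400), 600,
       quads = c(12, 18, 22, 35), quad_sd = rep(8, 4))
  )

  if (isTRUE(mri_dominant_hc_cmci)) {
    cog <- measure_specs()$measure[measure_specs()$modality == "cognitive"]
    for (m in cog) {
      hc <- trajectory$subgroup == "HC" & trajectory$measure == m
      cm <- trajectory$subgroup == "cMCI" & trajectory$measure == m
      trajectory[cm, c("intercept_mean", "intercept_sd", "slope_mean",
                       "slope_sd")] <-
        trajectory[hc, c("intercept_mean", "intercept_sd", "slope_mean",
                         "slope_sd")]
    }
    # widen the HC/cMCI gap in structural decline rates
    adj <- function(m, slope, slope_sd = NULL, quad = NULL) {
      i <- trajectory$subgroup == "cMCI" & trajectory$measure == m
      trajectory$slope_mean[i] <<- slope
      if (!is.null(slope_sd)) trajectory$slope_sd[i] <<- slope_sd
      if (!is.null(quad)) trajectory$quad_mean[i] <<- quad
    }
    adj("hippo_lh", -70, 12); adj("hippo_rh", -70, 12)
    adj("entorhinal_lh", -0.048, 0.009); adj("entorhinal_rh", -0.048, 0.009)
    adj("ventricle_lh", 1000, 250, quad = 30)
    adj("ventricle_rh", 1000, 250, quad = 30)
  }

  clip_ranges <- list(
    ravlt_im = c(0, 75), ravlt_pf = c(-50, 150), adas13 = c(0, 85),
    hippo_lh = c(1, Inf), hippo_rh = c(1, Inf),
    entorhinal_lh = c(0.5, Inf), entorhinal_rh = c(0.5, Inf),
    ventricle_lh = c(1, Inf), ventricle_rh = c(1, Inf)
  )

  config <- list(
    n_per_group = n_per_group,
    baseline_age = list(mean = 76, sd = 7),
    sex_ratio = 0.41,                     # fraction female
    education = list(mean = 16, sd = 2.7),
    etiv = list(mean = 1.5e6, sd = 1.4e5),
    visit_schedule = visit_schedule,
    trajectory = trajectory,
    # inter-visit intervals ~ Gamma(shape, mean_interval/shape): CV = 0.5
    interval_shape = 4,
    cross_measure_rho = cross_measure_rho,
    clip_ranges = clip_ranges,
    seed = as.integer(seed)
  )
  class(config) <- "cohort_config"
  validate_config(config)
  config
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a \code{cohort_config}: positive
#' group sizes, non-negative SDs, visit-count means at least 2 (every
#' subject must have two time points per modality), known subgroups and
#' measures, and a quadratic term only on measures registered as order 2.
#'
#' @param config A \code{cohort_config}.
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  n <- config$n_per_group
  if (is.null(names(n)) || !setequal(names(n), subgroup_levels())) {
    stop("n_per_group must be named with the four subgroups ",
         paste(subgroup_levels(), collapse = ", "), call. = FALSE)
  }
  if (any(n <= 0)) stop("n_per_group entries must be positive", call. = FALSE)
  vs <- config$visit_schedule
  if (any(vs$mean_count < 2)) {
    stop("visit_schedule mean_count must be >= 2 (two time points required)",
         call. = FALSE)
  }
  if (any(vs$mean_interval <= 0)) {
    stop("visit_schedule mean_interval must be positive", call. = FALSE)
  }
  tr <- config$trajectory
  sds <- c(tr$intercept_sd, tr$slope_sd, tr$quad_sd, tr$resid_sd,
           config$baseline_age$sd, config$education$sd, config$etiv$sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (!all(tr$measure %in% measure_specs()$measure)) {
    stop("trajectory table contains unknown measures", call. = FALSE)
  }
  specs <- measure_specs()
  lin <- specs$measure[specs$polynomial_order == 1L]
  bad <- tr$measure %in% lin & (tr$quad_mean != 0 | tr$quad_sd != 0)
  if (any(bad)) {
    stop("quadratic terms configured for linear measures: ",
         paste(unique(tr$measure[bad]), collapse = ", "), call. = FALSE)
  }
  if (config$cross_measure_rho < 0 || config$cross_measure_rho > 1) {
    stop("cross_measure_rho must be in [0, 1]", call. = FALSE)
  }
  invisible(config)
}

# ---- flat key-value (dotted-key YAML) serialization ------------------------

flatten_config <- function(config) {
  out <- list()
  put <- function(key, value) out[[key]] <<- value
  put("seed", config$seed)
  put("sex_ratio", config$sex_ratio)
  put("interval_shape", config$interval_shape)
  put("cross_measure_rho", config$cross_measure_rho)
  for (g in names(config$n_per_group)) {
    put(paste0("n_per_group.", g), unname(config$n_per_group[[g]]))
  }
  for (f in c("baseline_age", "education", "etiv")) {
    put(paste0(f, ".mean"), config[[f]]$mean)
    put(paste0(f, ".sd"), config[[f]]$sd)
  }
  vs <- config$visit_schedule
  for (i in seq_len(nrow(vs))) {
    key <- paste("visit_schedule", vs$subgroup[i], vs$modality[i], sep = ".")
    put(paste0(key, ".mean_count"), vs$mean_count[i])
    put(paste0(key, ".mean_interval"), vs$mean_interval[i])
  }
  tr <- config$trajectory
  for (i in seq_len(nrow(tr))) {
    key <- paste("trajectory", tr$subgroup[i], tr$measure[i], sep = ".")
    for (f in c("intercept_mean", "intercept_sd", "slope_mean", "slope_sd",
                "quad_mean", "quad_sd", "resid_sd")) {
      put(paste(key, f, sep = "."), tr[[f]][i])
    }
  }
  for (m in names(config$clip_ranges)) {
    put(paste0("clip.", m, ".lo"), config$clip_ranges[[m]][1])
    put(paste0("clip.", m, ".hi"), config$clip_ranges[[m]][2])
  }
  out
}

#' Write / read a cohort configuration
#'
#' The on-disk format is a flat YAML document whose keys are dotted paths
#' (e.g. \code{trajectory.cAD.adas13.slope_mean}), one scalar per key, so
#' configs diff cleanly and can be edited by hand.
#'
#' @param config A \code{cohort_config}.
#' @param path File path.
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns a \code{cohort_config}.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  flat <- flatten_config(config)
  # +/-Inf are not portable YAML scalars; tag them
  flat <- lapply(flat, function(v) if (is.infinite(v)) paste0(sign(v), "Inf") else v)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  num <- function(v) {
    if (identical(v, "1Inf")) return(Inf)
    if (identical(v, "-1Inf")) return(-Inf)
    as.numeric(v)
  }
  config <- default_config()           # template for structure
  config$seed <- as.integer(flat$seed)
  config$sex_ratio <- num(flat$sex_ratio)
  config$interval_shape <- num(flat$interval_shape)
  config$cross_measure_rho <- num(flat$cross_measure_rho)
  for (g in subgroup_levels()) {
    config$n_per_group[[g]] <- as.integer(flat[[paste0("n_per_group.", g)]])
  }
  for (f in c("baseline_age", "education", "etiv")) {
    config[[f]]$mean <- num(flat[[paste0(f, ".mean")]])
    config[[f]]$sd <- num(flat[[paste0(f, ".sd")]])
  }
  vs <- config$visit_schedule
  for (i in seq_len(nrow(vs))) {
    key <- paste("visit_schedule", vs$subgroup[i], vs$modality[i], sep = ".")
    vs$mean_count[i] <- num(flat[[paste0(key, ".mean_count")]])
    vs$mean_interval[i] <- num(flat[[paste0(key, ".mean_interval")]])
  }
  config$visit_schedule <- vs
  tr <- config$trajectory
  for (i in seq_len(nrow(tr))) {
    key <- paste("trajectory", tr$subgroup[i], tr$measure[i], sep = ".")
    for (f in c("intercept_mean", "intercept_sd", "slope_mean", "slope_sd",
                "quad_mean", "quad_sd", "resid_sd")) {
      tr[[f]][i] <- num(flat[[paste(key, f, sep = ".")]])
    }
  }
  config$trajectory <- tr
  for (m in names(config$clip_ranges)) {
    config$clip_ranges[[m]] <- c(num(flat[[paste0("clip.", m, ".lo")]]),
                                 num(flat[[paste0("clip.", m, ".hi")]]))
  }
  validate_config(config)
  config
}
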