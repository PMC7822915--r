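#' Generate a synthetic longitudinal cohort
#'
#' Simulates four longitudinal subgroups — stable healthy controls (HC),
#' controls who convert to MCI (cMCI), stable MCI (sMCI), and MCI subjects
#' who convert to AD (cAD) — with the statistical structure the downstream
#' trajectory analysis assumes:
#' \itemize{
#'   \item irregular per-subject visit schedules, sampled independently for
#'     the cognitive and MRI modalities: visit counts are 2 + Poisson
#'     (matching the configured mean), inter-visit intervals are Gamma with
#'     the configured mean and shape \code{interval_shape};
#'   \item per (subgroup, measure) trajectories: subject intercept, slope
#'     (and quadratic term for ventricles) drawn from between-subject normal
#'     distributions around the group means, plus i.i.d. Gaussian residual
#'     noise per visit, all as functions of age centred at the reference age
#'     \code{baseline_age$mean};
#'   \item converters switch diagnosis at a conversion visit drawn uniformly
#'     between the second and penultimate cognitive visit (so at least one
#'     pre-conversion visit always exists); MRI visits at or after the
#'     conversion age carry the converted diagnosis too;
#'   \item a per-subject eTIV (constant across visits) for later volume
#'     normalization.
#' }
#' Values are clipped to the configured plausible ranges (e.g. RAVLT
#' immediate recall to [0, 75]). Generation is fully deterministic given the
#' config, including its seed.
#'
#' @param config A \code{cohort_config}, e.g. \code{\link{default_config}()}.
#' @return A long-format data.frame, one row per subject-visit-measure, with
#'   columns \code{subject_id}, \code{sex} (\code{"f"}/\code{"m"}),
#'   \code{education}, \code{subgroup}, \code{modality}, \code{visit_index},
#'   \code{age}, \code{diagnosis}, \code{measure}, \code{value}, \code{etiv}
#'   (NA on cognitive rows).
#' @examples
#' cfg <- default_config(n_per_group = c(HC = 5, cMCI = 5, sMCI = 5, cAD = 5))
#' cohort <- generate_cohort(cfg)
#' head(cohort)
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  specs <- measure_specs()
  rho <- config$cross_measure_rho
  out <- vector("list", sum(config$n_per_group))
  k <- 0L

  for (g in subgroup_levels()) {
    diag_rule <- subgroup_diagnoses(g)
    tr_g <- config$trajectory[config$trajectory$subgroup == g, ]
    vs_g <- config$visit_schedule[config$visit_schedule$subgroup == g, ]
    for (s in seq_len(config$n_per_group[[g]])) {
      k <- k + 1L
      id <- sprintf("%s_%04d", g, s)
      sex <- if (runif(1) < config$sex_ratio) "f" else "m"
      edu <- round(max(6, min(20, rnorm(1, config$education$mean,
                                        config$education$sd))))
      age0 <- rnorm(1, config$baseline_age$mean, config$baseline_age$sd)
      etiv <- max(1e5, rnorm(1, config$etiv$mean, config$etiv$sd))

      sched <- lapply(c(cognitive = "cognitive", mri = "mri"), function(mod) {
        row <- vs_g[vs_g$modality == mod, ]
        n_vis <- 2L + rpois(1, row$mean_count - 2)
        gaps <- rgamma(n_vis - 1L, shape = config$interval_shape,
                       scale = row$mean_interval / config$interval_shape)
        age0 + c(0, cumsum(gaps))
      })

      # conversion visit: uniform over cognitive visits 2..(n-1); with only
      # two visits the last visit is the only admissible choice
      conv_age <- NA_real_
      if (diag_rule$converter) {
        n_cog <- length(sched$cognitive)
        candidates <- 2:max(2L, n_cog - 1L)
        idx <- candidates[sample.int(length(candidates), 1L)]
        conv_age <- sched$cognitive[idx]
      }
      diag_at <- function(ages) {
        if (!diag_rule$converter) rep(diag_rule$pre, length(ages))
        else ifelse(ages >= conv_age, diag_rule$post, diag_rule$pre)
      }

      # latent severity factor shared across measures (cross_measure_rho)
      z <- rnorm(1)
      rows <- vector("list", nrow(specs))
      for (mi in seq_len(nrow(specs))) {
        sp <- specs[mi, ]
        p <- tr_g[tr_g$measure == sp$measure, ]
        dirn <- if (sp$impairment_direction == "higher-is-worse") 1 else -1
        mix <- function(mean, sd1) {
          mean + sd1 * (rho * dirn * z + sqrt(1 - rho^2) * rnorm(1))
        }
        a_i <- mix(p$intercept_mean, p$intercept_sd)
        s_i <- mix(p$slope_mean, p$slope_sd)
        q_i <- if (sp$polynomial_order == 2L) mix(p$quad_mean, p$quad_sd) else 0
        ages <- sched[[sp$modality]]
        dt <- ages - config$baseline_age$mean
        vals <- a_i + s_i * dt + q_i * dt^2 +
          rnorm(length(ages), 0, p$resid_sd)
        clip <- config$clip_ranges[[sp$measure]]
        vals <- pmin(pmax(vals, clip[1]), clip[2])
        rows[[mi]] <- data.frame(
          subject_id = id, sex = sex, education = edu, subgroup = g,
          modality = sp$modality, visit_index = seq_along(ages),
          age = ages, diagnosis = diag_at(ages), measure = sp$measure,
          value = vals,
          etiv = if (sp$modality == "mri") etiv else NA_real_,
          stringsAsFactors = FALSE
        )
      }
      out[[k]] <- do.call(rbind, rows)
    }
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  cohort
}

#' Per-subject summary of a cohort
#'
#' One row per subject: sex, education, subgroup, baseline and last-visit
#' ages, visit counts per modality, and conversion age (the age at the first
#' visit carrying the converted diagnosis; NA for stable subjects).
#'
#' @param cohort Long-format cohort data.frame.
#' @return A data.frame with one row per subject.
#' @export
subject_summary <- function(cohort) {
  split_rows <- split(cohort, cohort$subject_id)
  rows <- lapply(split_rows, function(d) {
    conv <- conversion_age(d)
    data.frame(
      subject_id = d$subject_id[1], sex = d$sex[1],
      education = d$education[1], subgroup = d$subgroup[1],
      baseline_age = min(d$age), last_age = max(d$age),
      n_cognitive = length(unique(d$age[d$modality == "cognitive"])),
      n_mri = length(unique(d$age[d$modality == "mri"])),
      conversion_age = conv, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Age at the first visit with the converted diagnosis, NA for stable groups.
conversion_age <- function(subject_rows) {
  g <- subject_rows$subgroup[1]
  rule <- subgroup_diagnoses(g)
  if (!rule$converter) return(NA_real_)
  conv_rows <- subject_rows$age[subject_rows$diagnosis == rule$post]
  if (length(conv_rows) == 0L) return(NA_real_)
  min(conv_rows)
}

#' Write / read a cohort as long-format CSV
#'
#' The file has exactly the columns
#' \code{subject_id,sex,education,subgroup,modality,visit_index,age,diagnosis,measure,value,etiv},
#' ages with 4 decimal places, and empty \code{etiv} on cognitive rows.
#' \code{read_cohort} validates the file and reports malformed rows by
#' number: unknown diagnosis or subgroup codes, non-positive eTIV on MRI
#' rows, and ages that decrease within a subject's modality stream.
#'
#' @param cohort Long-format cohort data.frame.
#' @param path CSV file path.
#' @return \code{write_cohort}: \code{path}, invisibly. \code{read_cohort}:
#'   the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$age <- sprintf("%.4f", out$age)
  out$etiv <- ifelse(is.na(out$etiv), "", sprintf("%.1f", out$etiv))
  cols <- c("subject_id", "sex", "education", "subgroup", "modality",
            "visit_index", "age", "diagnosis", "measure", "value", "etiv")
  write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(etiv = "character"))
  if (nrow(raw) == 0L) stop("no records in ", path, call. = FALSE)
  expected <- c("subject_id", "sex", "education", "subgroup", "modality",
                "visit_index", "age", "diagnosis", "measure", "value", "etiv")
  if (!identical(names(raw), expected)) {
    stop("malformed cohort file: expected header ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  raw$etiv <- suppressWarnings(as.numeric(ifelse(raw$etiv == "",
                                                 NA_character_, raw$etiv)))
  bad_diag <- which(!raw$diagnosis %in% c("CN", "MCI", "AD"))
  if (length(bad_diag)) {
    stop("unknown diagnosis code at row(s) ",
         paste(head(bad_diag, 5), collapse = ", "), call. = FALSE)
  }
  bad_grp <- which(!raw$subgroup %in% subgroup_levels())
  if (length(bad_grp)) {
    stop("unknown subgroup at row(s) ",
         paste(head(bad_grp, 5), collapse = ", "), call. = FALSE)
  }
  bad_etiv <- which(raw$modality == "mri" &
                      (is.na(raw$etiv) | raw$etiv <= 0))
  if (length(bad_etiv)) {
    stop("missing or non-positive etiv on MRI row(s) ",
         paste(head(bad_etiv, 5), collapse = ", "), call. = FALSE)
  }
  # within each subject+modality stream, visit order must have
  # non-decreasing age
  key <- paste(raw$subject_id, raw$modality, raw$measure)
  for (d in split(seq_len(nrow(raw)), key)) {
    idx <- d[order(raw$visit_index[d])]
    if (is.unsorted(raw$age[idx])) {
      stop("age decreases within subject ", raw$subject_id[idx[1]],
           " (", raw$modality[idx[1]], ")", call. = FALSE)
    }
  }
  raw
}
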