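#' Measure registry
#'
#' Returns one specification row per measure used in the pipeline: three
#' cognitive test scores (RAVLT immediate recall, RAVLT percent forgetting,
#' ADAS13) and six regional MRI measures (hippocampal and lateral-ventricle
#' volumes, entorhinal cortical thickness; left and right hemispheres).
#'
#' Lateral ventricle volumes grow non-linearly with age at the cohort level,
#' so they are modelled with a quadratic age term (\code{polynomial_order
#' = 2}); all other measures are linear. Volumes (but not thickness or test
#' scores) are normalized by estimated total intracranial volume (eTIV)
#' before model fitting, which removes head-size and much of the sex
#' difference in raw volumes.
#'
#' @return A data.frame with columns \code{measure}, \code{modality}
#'   (\code{"cognitive"} or \code{"mri"}), \code{polynomial_order} (1 or 2),
#'   \code{impairment_direction} (\code{"lower-is-worse"} or
#'   \code{"higher-is-worse"}), and \code{normalize_by_etiv} (logical).
#' @examples
#' measure_specs()
#' @export
measure_specs <- function() {
  specs <- data.frame(
    measure = c("ravlt_im", "ravlt_pf", "adas13",
                "hippo_lh", "hippo_rh",
                "entorhinal_lh", "entorhinal_rh",
                "ventricle_lh", "ventricle_rh"),
    modality = c(rep("cognitive", 3), rep("mri", 6)),
    polynomial_order = c(rep(1L, 7), 2L, 2L),
    impairment_direction = c("lower-is-worse", "higher-is-worse",
                             "higher-is-worse",
                             "lower-is-worse", "lower-is-worse",
                             "lower-is-worse", "lower-is-worse",
                             "higher-is-worse", "higher-is-worse"),
    normalize_by_etiv = c(rep(FALSE, 3), TRUE, TRUE, FALSE, FALSE,
                          TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  specs
}

#' @rdname measure_specs
#' @param measure Measure name.
#' @export
measure_spec <- function(measure) {
  specs <- measure_specs()
  row <- specs[specs$measure == measure, ]
  if (nrow(row) != 1L) {
    stop("unknown measure: ", measure, call. = FALSE)
  }
  row
}

subgroup_levels <- function() c("HC", "cMCI", "sMCI", "cAD")

#' Diagnosis sequence implied by a longitudinal subgroup
#'
#' HC subjects are cognitively normal (CN) at every visit, cMCI subjects
#' start CN and convert to MCI, sMCI subjects are MCI throughout, and cAD
#' subjects start MCI and convert to AD.
#'
#' @param subgroup One of \code{"HC"}, \code{"cMCI"}, \code{"sMCI"},
#'   \code{"cAD"}.
#' @return A list with elements \code{pre} and \code{post} (diagnosis codes
#'   before and from conversion; identical for stable groups) and
#'   \code{converter} (logical).
#' @export
subgroup_diagnoses <- function(subgroup) {
  switch(subgroup,
    HC   = list(pre = "CN",  post = "CN",  converter = FALSE),
    cMCI = list(pre = "CN",  post = "MCI", converter = TRUE),
    sMCI = list(pre = "MCI", post = "MCI", converter = FALSE),
    cAD  = list(pre = "MCI", post = "AD",  converter = TRUE),
    stop("unknown subgroup: ", subgroup, call. = FALSE)
  )
}
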