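#' Published validation-cohort summary tables
#'
#' Per-ISS-level summary statistics and outcome counts from the prospective
#' validation cohort of 235 diabetic foot wound patients (159 non-ischaemic,
#' 24 mild, 25 moderate, 27 severe).  These summaries are the calibration
#' targets for \code{\link{cohort_params}} and the fixtures for the rate
#' tables: individual patient data were not published.
#'
#' @return a list with components
#' \describe{
#'   \item{level_n}{integer vector, patients per ISS level 0--3.}
#'   \item{baseline}{data.frame of per-level means and SDs for the continuous
#'     baseline variables (age, diabetes duration, HbA1c, wound history,
#'     wound size, SEWSS score sum).}
#'   \item{counts}{data.frame of per-level counts for the categorical rows:
#'     sex, smoking, palpable pulses (dorsalis pedis, tibialis posterior),
#'     and the four study outcomes (wound healing, major amputation,
#'     abandonment of treatment, early death).}
#'   \item{vascular}{data.frame of per-level means and SDs for the
#'     ankle/brachial and toe/brachial indices and, for levels 1--3, the
#'     ankle and toe systolic pressures.}
#' }
#' @export
reference_tables <- function() {
  level_n <- c(159L, 24L, 25L, 27L)
  baseline <- data.frame(
    variable = c("age", "diabetes_duration", "hba1c", "wound_history",
                 "wound_size", "sewss_sum"),
    mean0 = c(61.3, 17.7, 8.6, 5.8, 11.3, 14.6),
    sd0   = c(11.1,  8.9, 2.3, 7.5, 36.4,  3.7),
    mean1 = c(71.9, 22.6, 7.4, 8.6, 13.9, 15.6),
    sd1   = c( 9.5, 10.9, 2.3, 9.8, 22.3,  4.0),
    mean2 = c(69.0, 19.8, 8.0, 6.6, 19.8, 17.8),
    sd2   = c(10.5, 11.5, 1.9, 8.8, 36.5,  3.6),
    mean3 = c(71.3, 24.1, 7.8, 7.5, 19.1, 19.3),
    sd3   = c( 7.3, 12.7, 2.1, 5.8, 18.9,  3.2),
    stringsAsFactors = FALSE)
  counts <- data.frame(
    row = c("male", "smoking", "pulse_dorsalis_palpable",
            "pulse_tibialis_palpable", "wound_healing", "major_amputation",
            "abandonment", "early_death"),
    n0 = c(68L, 52L, 112L, 103L, 134L,  7L, 28L, 3L),
    n1 = c(14L,  6L,  12L,  10L,  15L,  3L,  7L, 0L),
    n2 = c(13L,  6L,   2L,   1L,  11L,  4L,  9L, 2L),
    n3 = c(14L,  7L,   0L,   0L,   4L, 19L, 13L, 1L),
    stringsAsFactors = FALSE)
  vascular <- data.frame(
    variable = c("abi", "tbi", "ankle_pressure", "toe_pressure"),
    mean0 = c(1.10, 0.90, NA, NA),
    sd0   = c(0.10, 0.35, NA, NA),
    mean1 = c(0.86, 0.62, 124.0, 91.5),
    sd1   = c(0.30, 0.52,  44.4, 62.3),
    mean2 = c(0.68, 0.50, 125.0, 81.3),
    sd2   = c(0.20, 0.33,  58.7, 77.4),
    mean3 = c(0.47, 0.10,  95.0, 26.5),
    sd3   = c(0.20, 0.42,  61.8, 48.2),
    stringsAsFactors = FALSE)
  list(level_n = level_n, baseline = baseline, counts = counts,
       vascular = vascular)
}
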