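#' @title Ischaemia Severity Scale (ISS) scoring
#' @description Functions that derive the ankle/brachial and toe/brachial
#'   indices from raw systolic pressures, categorise each non-invasive
#'   vascular test onto the ordinal 0--3 ischaemia severity scale, reconcile
#'   discrepant tests by a precedence order, and compute Saint Elian wound
#'   score sums and grades.
#' @name iss-scoring
NULL

#' ISS level labels
#'
#' @return character vector of the four level labels, index = level + 1.
#' @export
iss_labels <- function() c("non-ischaemic", "mild", "moderate", "severe")

#' Scoring configuration
#'
#' Band tables and test precedence used by the ISS categorisation functions.
#' The defaults encode the published scale: ABI 0.9--1.2 normal, 0.7--0.89
#' mild, 0.5--0.69 moderate, below 0.5 severe, above 1.2 incompressible
#' (Moenckeberg medial calcification, not classifiable by ABI); TBI at least
#' 0.75 normal, 0.60--0.74 mild, 0.30--0.59 moderate, below 0.30 severe.
#' Band gaps in the published wording (0.89 to 0.9) are closed with
#' half-open intervals so every non-negative index is classified.
#'
#' @param abi_bands numeric vector of lower cut points for levels 3,2,1,0
#'   given as \code{c(severe_upper, moderate_upper, mild_upper)}; an ABI in
#'   \code{[0, severe_upper)} scores 3, \code{[severe_upper, moderate_upper)}
#'   scores 2, \code{[moderate_upper, mild_upper)} scores 1 and
#'   \code{[mild_upper, incompressible_above]} scores 0.
#' @param tbi_bands same layout for the toe/brachial index.
#' @param incompressible_above ABI above this value is flagged incompressible
#'   and not classifiable by ABI (default 1.2).
#' @param waveform_map named integer vector mapping Doppler waveform
#'   categories to levels.
#' @param test_precedence character vector, most reliable test first, used by
#'   \code{\link{resolve_iss}}.
#' @return list of class \code{sewss_scoring_config}.
#' @export
scoring_config <- function(abi_bands = c(0.5, 0.7, 0.9),
                           tbi_bands = c(0.30, 0.60, 0.75),
                           incompressible_above = 1.2,
                           waveform_map = c(triphasic = 0L, biphasic = 1L,
                                            monophasic = 2L, absent = 3L),
                           test_precedence = c("waveform", "tbi", "abi", "pulse")) {
  stopifnot(length(abi_bands) == 3, !is.unsorted(abi_bands),
            length(tbi_bands) == 3, !is.unsorted(tbi_bands),
            incompressible_above > abi_bands[3],
            all(waveform_map %in% 0:3),
            all(test_precedence %in% c("waveform", "tbi", "abi", "pulse")))
  structure(list(abi_bands = abi_bands, tbi_bands = tbi_bands,
                 incompressible_above = incompressible_above,
                 waveform_map = waveform_map,
                 test_precedence = test_precedence),
            class = "sewss_scoring_config")
}

#' Ankle/brachial index from raw systolic pressures
#'
#' Uses the high ankle pressure (HAP) convention: the larger of the dorsalis
#' pedis and tibialis posterior systolic pressures is divided by the maximum
#' arm systolic pressure.  A ratio above \code{incompressible_above}
#' (default 1.2) is flagged incompressible.
#'
#' All arguments are vectorised; \code{NA} marks a missing measurement.
#'
#' @param ankle_dp,ankle_tp dorsalis pedis / tibialis posterior ankle
#'   systolic pressures, mmHg, \code{NA} if not measured.
#' @param arm_left,arm_right arm systolic pressures, mmHg, must be positive.
#' @param incompressible_above incompressibility threshold for the ratio.
#' @return data.frame with columns \code{abi} and \code{incompressible}.
#'   \code{abi} is \code{NA} when both ankle pressures are missing.
#' @examples
#' compute_abi(120, 100, 100, 95)   # HAP 120 / 100 = 1.20
#' compute_abi(55, 47, 100, 110)    # 0.50
#' @export
compute_abi <- function(ankle_dp, ankle_tp, arm_left, arm_right,
                        incompressible_above = 1.2) {
  n <- max(length(ankle_dp), length(ankle_tp), length(arm_left), length(arm_right))
  ankle_dp <- rep_len(ankle_dp, n); ankle_tp <- rep_len(ankle_tp, n)
  arm_left <- rep_len(arm_left, n); arm_right <- rep_len(arm_right, n)
  if (any(is.na(arm_left) | is.na(arm_right) | arm_left <= 0 | arm_right <= 0))
    stop_sewss("arm systolic pressures must be present and positive")
  if (any(c(ankle_dp, ankle_tp) < 0, na.rm = TRUE))
    stop_sewss("ankle pressures must be non-negative")
  if (any(is.na(ankle_dp) & is.na(ankle_tp)))
    stop_sewss("no ankle measurement: both ankle pressures missing")
  hap <- pmax(ankle_dp, ankle_tp, na.rm = TRUE)
  abi <- hap / pmax(arm_left, arm_right)
  data.frame(abi = abi,
             incompressible = !is.na(abi) & abi > incompressible_above)
}

#' Toe/brachial index from raw systolic pressures
#'
#' Hallux systolic pressure divided by the maximum arm systolic pressure.
#' A missing toe pressure yields \code{NA} (toe pressure cannot be measured
#' after a first-ray amputation or with a hallux wound; this is recorded,
#' not fatal).
#'
#' @param toe hallux systolic pressure, mmHg, \code{NA} if not measurable.
#' @param arm_left,arm_right arm systolic pressures, mmHg, must be positive.
#' @return numeric vector of TBI values.
#' @examples
#' compute_tbi(90, 100, 95)   # 0.90
#' @export
compute_tbi <- function(toe, arm_left, arm_right) {
  n <- max(length(toe), length(arm_left), length(arm_right))
  toe <- rep_len(toe, n)
  arm_left <- rep_len(arm_left, n); arm_right <- rep_len(arm_right, n)
  if (any(is.na(arm_left) | is.na(arm_right) | arm_left <= 0 | arm_right <= 0))
    stop_sewss("arm systolic pressures must be present and positive")
  if (any(toe < 0, na.rm = TRUE))
    stop_sewss("toe pressure must be non-negative")
  toe / pmax(arm_left, arm_right)
}

iss_level_result <- function(level, decided_by) {
  data.frame(level = as.integer(level),
             label = ifelse(is.na(level), NA_character_, iss_labels()[level + 1L]),
             decided_by = decided_by,
             stringsAsFactors = FALSE)
}

#' ISS level from pedal pulse palpation
#'
#' Palpation grades per artery: 0 bound strong pulse (non-ischaemic),
#' 1 palpable but slightly diminished (mild), 2 thready and scarcely
#' palpable (moderate), 3 non-palpable (severe).  The two foot arteries are
#' reconciled by taking the worse (maximum) grade.
#'
#' @param grade_dp,grade_tp palpation grades 0--3 for the dorsalis pedis and
#'   tibialis posterior arteries, \code{NA} if not assessed.
#' @return data.frame with \code{level}, \code{label}, \code{decided_by}.
#' @export
iss_from_pulse <- function(grade_dp, grade_tp = NA) {
  n <- max(length(grade_dp), length(grade_tp))
  grade_dp <- rep_len(grade_dp, n); grade_tp <- rep_len(grade_tp, n)
  g <- c(grade_dp, grade_tp)
  if (any(!is.na(g) & (g < 0 | g > 3 | g != floor(g))))
    stop_sewss("pulse palpation grades must be integers in 0..3")
  if (any(is.na(grade_dp) & is.na(grade_tp)))
    stop_sewss("no pulse assessment: both artery grades missing")
  lev <- pmax(grade_dp, grade_tp, na.rm = TRUE)
  iss_level_result(lev, "pulse")
}

#' ISS level from the ankle/brachial index
#'
#' Bands (half-open so the non-negative axis is partitioned):
#' \code{[0.9, 1.2]} level 0, \code{[0.7, 0.9)} level 1, \code{[0.5, 0.7)}
#' level 2, \code{[0, 0.5)} level 3.  An ABI above 1.2 is incompressible and
#' returns \code{NA} ("not classifiable by ABI"): classification defers to
#' the other tests.
#'
#' @param abi ankle/brachial index, non-negative.
#' @param config a \code{\link{scoring_config}}.
#' @return data.frame with \code{level} (NA when incompressible),
#'   \code{label}, \code{decided_by}.
#' @export
iss_from_abi <- function(abi, config = scoring_config()) {
  if (any(abi < 0, na.rm = TRUE)) stop_sewss("ABI must be non-negative")
  b <- config$abi_bands
  lev <- ifelse(is.na(abi) | abi > config$incompressible_above, NA_integer_,
         ifelse(abi >= b[3], 0L,
         ifelse(abi >= b[2], 1L,
         ifelse(abi >= b[1], 2L, 3L))))
  iss_level_result(lev, "abi")
}

#' ISS level from the toe/brachial index
#'
#' Bands: \code{[0.75, Inf)} level 0, \code{[0.60, 0.75)} level 1,
#' \code{[0.30, 0.60)} level 2, \code{[0, 0.30)} level 3.  The TBI is robust
#' to medial calcification, so there is no incompressible branch.
#'
#' @inheritParams iss_from_abi
#' @param tbi toe/brachial index, non-negative.
#' @export
iss_from_tbi <- function(tbi, config = scoring_config()) {
  if (any(tbi < 0, na.rm = TRUE)) stop_sewss("TBI must be non-negative")
  b <- config$tbi_bands
  lev <- ifelse(is.na(tbi), NA_integer_,
         ifelse(tbi >= b[3], 0L,
         ifelse(tbi >= b[2], 1L,
         ifelse(tbi >= b[1], 2L, 3L))))
  iss_level_result(lev, "tbi")
}

#' ISS level from the Doppler waveform category
#'
#' Maps the arterial flow trace category onto the scale: triphasic (normal)
#' 0, biphasic 1, monophasic 2, absent 3.
#'
#' @param w character vector of waveform categories, \code{NA} if the trace
#'   was not recorded.
#' @inheritParams iss_from_abi
#' @export
iss_from_waveform <- function(w, config = scoring_config()) {
  map <- config$waveform_map
  bad <- !is.na(w) & !(w %in% names(map))
  if (any(bad))
    stop_sewss("unknown waveform category: ", paste(unique(w[bad]), collapse = ", "))
  lev <- ifelse(is.na(w), NA_integer_, map[w])
  iss_level_result(lev, "waveform")
}

#' Resolve the ISS level from all available tests
#'
#' When the tests disagree, the classification of the test with the highest
#' reputed accuracy wins; the default precedence is waveform > TBI > ABI >
#' pulse palpation.  An incompressible ABI is skipped rather than classified.
#'
#' @param assessment data.frame (one row per patient/limb) with any of the
#'   columns \code{pulse_dorsalis}, \code{pulse_tibialis},
#'   \code{arm_systolic_left}, \code{arm_systolic_right},
#'   \code{ankle_systolic_dp}, \code{ankle_systolic_tp}, \code{toe_systolic},
#'   \code{waveform}, or pre-computed \code{abi} / \code{tbi}.  Indices are
#'   derived from the raw pressures when not supplied.
#' @param config a \code{\link{scoring_config}}.
#' @return data.frame with \code{level}, \code{label} and \code{decided_by}
#'   (the winning test).  A patient with no classifiable test raises an
#'   error ("unassessable") unless \code{na_unassessable = TRUE}.
#' @param na_unassessable return \code{NA} for unassessable rows instead of
#'   erroring.
#' @export
resolve_iss <- function(assessment, config = scoring_config(),
                        na_unassessable = FALSE) {
  a <- assessment
  n <- nrow(a)
  col <- function(nm) if (nm %in% names(a)) a[[nm]] else rep(NA, n)

  abi <- as.numeric(col("abi"))
  ok <- is.na(abi) &
    !(is.na(col("ankle_systolic_dp")) & is.na(col("ankle_systolic_tp")))
  if (any(ok)) {
    r <- compute_abi(col("ankle_systolic_dp")[ok], col("ankle_systolic_tp")[ok],
                     col("arm_systolic_left")[ok], col("arm_systolic_right")[ok],
                     config$incompressible_above)
    abi[ok] <- r$abi
  }

  tbi <- as.numeric(col("tbi"))
  ok <- is.na(tbi) & !is.na(col("toe_systolic"))
  if (any(ok))
    tbi[ok] <- compute_tbi(col("toe_systolic")[ok],
                           col("arm_systolic_left")[ok], col("arm_systolic_right")[ok])

  per_test <- list(
    waveform = iss_from_waveform(col("waveform"), config)$level,
    tbi      = iss_from_tbi(tbi, config)$level,
    abi      = iss_from_abi(abi, config)$level,  # NA where incompressible
    pulse    = {
      dp <- col("pulse_dorsalis"); tp <- col("pulse_tibialis")
      lev <- rep(NA_integer_, n)
      ok <- !(is.na(dp) & is.na(tp))
      if (any(ok)) lev[ok] <- iss_from_pulse(dp[ok], tp[ok])$level
      lev
    })

  level <- rep(NA_integer_, n)
  decided_by <- rep(NA_character_, n)
  for (test in config$test_precedence) {
    take <- is.na(level) & !is.na(per_test[[test]])
    level[take] <- per_test[[test]][take]
    decided_by[take] <- test
  }
  if (any(is.na(level)) && !na_unassessable)
    stop_sewss("unassessable patient: no classifiable vascular test in row(s) ",
               paste(utils::head(which(is.na(level)), 5), collapse = ", "))
  iss_level_result(level, decided_by)
}

#' Saint Elian wound score sum and grade
#'
#' The ten wound factors (primary location, topographic aspects, number of
#' affected zones, ischaemia, infection, oedema, neuropathy, depth, area,
#' healing phase) are each subscored 0--3; the sum (maximum 30) is banded
#' into grades: I for 10 points or fewer (mild, healing likely), II for
#' 11--20 (partial foot threatening), III for 21--30 (limb and life
#' threatening).
#'
#' @param subscores data.frame or matrix with ten integer columns in 0--3,
#'   one row per patient, or a numeric vector of length ten for a single
#'   patient.
#' @return data.frame with \code{score_sum} (0--30) and \code{grade}
#'   (ordered factor I < II < III).
#' @export
sewss_sum_and_grade <- function(subscores) {
  if (is.null(dim(subscores))) subscores <- matrix(subscores, nrow = 1)
  subscores <- as.matrix(subscores)
  if (ncol(subscores) != 10)
    stop_sewss("expected ten factor subscores, got ", ncol(subscores))
  if (any(is.na(subscores)) ||
      any(subscores < 0 | subscores > 3 | subscores != floor(subscores)))
    stop_sewss("subscores must be integers in 0..3")
  s <- as.integer(rowSums(subscores))
  grade <- cut(s, breaks = c(-1, 10, 20, 30), labels = c("I", "II", "III"),
               ordered_result = TRUE)
  data.frame(score_sum = s, grade = grade)
}

#' Names of the ten SEWSS factor columns
#' @return character vector of the cohort column names holding the subscores.
#' @export
sewss_factor_names <- function() {
  paste0("sewss_", c("location", "topography", "affected_zones", "ischaemia",
                     "infection", "oedema", "neuropathy", "depth", "area",
                     "healing_phase"))
}

#' Score a cohort table
#'
#' Adds derived columns to a flat per-patient cohort table: \code{abi},
#' \code{tbi} (from the raw pressures where absent), \code{iss},
#' \code{iss_label}, \code{iss_decided_by}, and, when the ten SEWSS factor
#' columns are present, \code{sewss_sum} and \code{sewss_grade}.
#'
#' @param cohort cohort data.frame (see \code{\link{read_cohort_csv}} for the
#'   schema).
#' @param config a \code{\link{scoring_config}}.
#' @param na_unassessable pass rows with no classifiable test through as
#'   \code{NA} instead of erroring.
#' @return the cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort, config = scoring_config(),
                         na_unassessable = FALSE) {
  n <- nrow(cohort)
  if (!"abi" %in% names(cohort)) cohort$abi <- NA_real_
  if (!"tbi" %in% names(cohort)) cohort$tbi <- NA_real_
  has_ankle <- !(is.na(cohort$ankle_systolic_dp %||% rep(NA, n)) &
                 is.na(cohort$ankle_systolic_tp %||% rep(NA, n)))
  if (any(is.na(cohort$abi) & has_ankle)) {
    i <- is.na(cohort$abi) & has_ankle
    r <- compute_abi(cohort$ankle_systolic_dp[i], cohort$ankle_systolic_tp[i],
                     cohort$arm_systolic_left[i], cohort$arm_systolic_right[i],
                     config$incompressible_above)
    cohort$abi[i] <- r$abi
  }
  if ("toe_systolic" %in% names(cohort)) {
    i <- is.na(cohort$tbi) & !is.na(cohort$toe_systolic)
    if (any(i))
      cohort$tbi[i] <- compute_tbi(cohort$toe_systolic[i],
                                   cohort$arm_systolic_left[i],
                                   cohort$arm_systolic_right[i])
  }
  res <- resolve_iss(cohort, config, na_unassessable = na_unassessable)
  cohort$iss <- res$level
  cohort$iss_label <- res$label
  cohort$iss_decided_by <- res$decided_by
  fac <- sewss_factor_names()
  if (all(fac %in% names(cohort))) {
    sg <- sewss_sum_and_grade(cohort[, fac])
    cohort$sewss_sum <- sg$score_sum
    cohort$sewss_grade <- as.character(sg$grade)
  }
  cohort
}
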