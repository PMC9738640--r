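#' Synthetic cohort parameters
#'
#' Assembles the generative model for a synthetic diabetic-foot-wound cohort.
#' Defaults are calibrated to the published per-ISS-level summary tables
#' (\code{\link{reference_tables}}): cohort composition 159/24/25/27 over
#' levels 0--3, per-level means and SDs for the continuous baselines and the
#' vascular indices, and per-level outcome probabilities derived from the
#' published outcome counts.
#'
#' The published outcome counts overlap (their per-level sums exceed the
#' column totals), so they cannot be used directly as a categorical
#' distribution.  The defaults take the healing probability from the printed
#' count over the column n and split the remaining probability across major
#' amputation, treatment abandonment and early death proportionally to their
#' printed counts; any residual is administrative censoring.
#'
#' @param n cohort size.
#' @param level_counts patients per ISS level in exact-count mode; must sum
#'   to \code{n}.
#' @param assignment \code{"exact"} (fixed per-level counts) or
#'   \code{"multinomial"} (each patient's level drawn from
#'   \code{level_counts / n}).
#' @param band_concordance probability that a patient's ABI, TBI and waveform
#'   draws are constrained to the band of their latent level; with the
#'   complementary probability the draw comes from the level's unconstrained
#'   marginal, producing realistic cross-test discrepancies.
#' @param toe_unmeasurable_prob probability that the toe pressure cannot be
#'   measured (first-ray amputation or hallux wound; 0.119 in the validation
#'   cohort).
#' @param waveform_present_prob per-level probability that a Doppler waveform
#'   trace was recorded (the study ran waveform analysis essentially only in
#'   patients already judged ischaemic).
#' @param pulse_error_prob probability that a palpation grade misses the
#'   latent level by one (split evenly up/down, clamped to 0--3).
#' @param arm_mean,arm_sd arm systolic pressure distribution, mmHg.
#' @param weibull_shape,weibull_scale shape (shared) and per-level scale
#'   (weeks) of the truncated Weibull time-to-healing model.
#' @param time_range truncation range of treatment-period times, weeks.
#' @param followup_weeks administrative follow-up horizon, weeks.
#' @param delayed_death_prob per-level probability of delayed (post
#'   follow-up) mortality, generated as a separate flag outside the primary
#'   time-to-healing model.
#' @param seed integer seed making the cohort reproducible.
#' @return list of class \code{sewss_cohort_params}.
#' @export
cohort_params <- function(n = 235L,
                          level_counts = c(159L, 24L, 25L, 27L),
                          assignment = c("exact", "multinomial"),
                          band_concordance = 0.95,
                          toe_unmeasurable_prob = 0.119,
                          waveform_present_prob = c(0.031, 1, 1, 1),
                          pulse_error_prob = 0.2,
                          arm_mean = 130, arm_sd = 15,
                          weibull_shape = 1.6,
                          weibull_scale = c(8, 12, 16, 22),
                          time_range = c(1, 30),
                          followup_weeks = 52,
                          delayed_death_prob = c(0.05, 0.10, 0.15, 0.25),
                          seed = NULL) {
  assignment <- match.arg(assignment)
  ref <- reference_tables()
  outcome_probs <- default_outcome_probs(ref)
  p <- list(n = as.integer(n), level_counts = as.integer(level_counts),
            level_proportions = if (sum(level_counts) > 0)
              level_counts / sum(level_counts) else rep(0.25, 4),
            assignment = assignment,
            band_concordance = band_concordance,
            toe_unmeasurable_prob = toe_unmeasurable_prob,
            waveform_present_prob = waveform_present_prob,
            pulse_error_prob = pulse_error_prob,
            arm_mean = arm_mean, arm_sd = arm_sd,
            weibull_shape = weibull_shape, weibull_scale = weibull_scale,
            time_range = time_range, followup_weeks = followup_weeks,
            delayed_death_prob = delayed_death_prob,
            baseline = ref$baseline, vascular = ref$vascular,
            counts = ref$counts, level_n_ref = ref$level_n,
            outcome_probs = outcome_probs,
            seed = seed)
  validate_cohort_params(p)
  structure(p, class = "sewss_cohort_params")
}

# healed from printed count / n; adverse outcomes share the residual
# probability proportionally to their printed counts (see ?cohort_params)
default_outcome_probs <- function(ref = reference_tables()) {
  cnt <- ref$counts
  nlev <- ref$level_n
  probs <- matrix(0, nrow = 4, ncol = 5,
                  dimnames = list(level = 0:3,
                                  outcome = c("healed", "major_amputation",
                                              "abandoned", "early_death",
                                              "censored")))
  rows <- c("wound_healing", "major_amputation", "abandonment", "early_death")
  for (l in 1:4) {
    k <- c(cnt[[paste0("n", l - 1)]][match(rows, cnt$row)])
    healed <- k[1] / nlev[l]
    adverse <- k[2:4]
    resid <- 1 - healed
    share <- if (sum(adverse) > 0) resid * adverse / sum(adverse) else rep(0, 3)
    probs[l, ] <- c(healed, share, max(0, 1 - healed - sum(share)))
  }
  probs
}

validate_cohort_params <- function(p) {
  stopifnot(p$n >= 0, length(p$level_counts) == 4, all(p$level_counts >= 0))
  if (p$assignment == "exact" && sum(p$level_counts) != p$n)
    stop_sewss("level_counts must sum to n in exact-count mode")
  if (abs(sum(p$level_proportions) - 1) > 1e-9)
    stop_sewss("level proportions must sum to 1")
  if (any(p$outcome_probs < -1e-12) ||
      any(abs(rowSums(p$outcome_probs) - 1) > 1e-9))
    stop_sewss("outcome probabilities per level must form a distribution")
  stopifnot(p$band_concordance >= 0, p$band_concordance <= 1,
            all(p$weibull_scale > 0), p$weibull_shape > 0,
            p$time_range[1] > 0, p$time_range[2] > p$time_range[1],
            all(c(p$baseline$sd0, p$baseline$sd1, p$baseline$sd2,
                  p$baseline$sd3) >= 0))
  invisible(p)
}

# per-level index bands matching the default scoring_config(), used to
# constrain concordant draws; row = level + 1, cols = lower, upper
iss_index_bands <- function(which = c("abi", "tbi"),
                            config = scoring_config()) {
  which <- match.arg(which)
  b <- if (which == "abi") config$abi_bands else config$tbi_bands
  upper0 <- if (which == "abi") config$incompressible_above else Inf
  rbind(`0` = c(b[3], upper0),
        `1` = c(b[2], b[3]),
        `2` = c(b[1], b[2]),
        `3` = c(0, b[1]))
}

level_param <- function(tab, variable, level) {
  i <- match(variable, tab$variable)
  c(mean = tab[[paste0("mean", level)]][i], sd = tab[[paste0("sd", level)]][i])
}

# lognormal parameters matched to a target mean and sd by moments
lognorm_par <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# distribute `total` points over k factors with a cap of 3 each, uniformly
# over the capacity slots (multivariate hypergeometric)
distribute_subscores <- function(total, k = 9, cap = 3) {
  total <- min(total, k * cap)
  if (total <= 0) return(integer(k))
  tabulate(sample(rep(seq_len(k), each = cap), total), nbins = k)
}

# vectorised block of n patients sharing one latent level
generate_level_block <- function(params, level, n) {
  p <- params
  lev <- as.character(level)
  bl <- function(v) level_param(p$baseline, v, level)
  vs <- function(v) level_param(p$vascular, v, level)

  age <- rtruncnorm(n, bl("age")[1], bl("age")[2], 18, 100)
  duration <- rtruncnorm(n, bl("diabetes_duration")[1], bl("diabetes_duration")[2], 0, 70)
  hba1c <- rtruncnorm(n, bl("hba1c")[1], bl("hba1c")[2], 4, 20)
  history <- rtruncnorm(n, bl("wound_history")[1], bl("wound_history")[2], 0, 104)
  ws <- bl("wound_size")
  if (ws[2] == 0) {
    wound_size <- rep(ws[1], n)
  } else {
    lp <- lognorm_par(ws[1], ws[2])
    wound_size <- stats::rlnorm(n, lp[1], lp[2])
  }
  cnt <- p$counts
  sex_p <- cnt[[paste0("n", level)]][match("male", cnt$row)] /
    p$level_n_ref[level + 1]
  smoke_p <- cnt[[paste0("n", level)]][match("smoking", cnt$row)] /
    p$level_n_ref[level + 1]
  sex <- ifelse(stats::runif(n) < sex_p, "male", "female")
  smoking <- stats::runif(n) < smoke_p

  arm_l <- rtruncnorm(n, p$arm_mean, p$arm_sd, 90, 200)
  arm_r <- rtruncnorm(n, p$arm_mean, p$arm_sd, 90, 200)
  arm_max <- pmax(arm_l, arm_r)

  # indices: concordant draws stay inside the latent level's band, the rest
  # come from the level's unconstrained (positive) marginal
  draw_index <- function(par, band) {
    inband <- stats::runif(n) < p$band_concordance
    x <- numeric(n)
    if (any(inband))
      x[inband] <- rtruncnorm(sum(inband), par[1], par[2],
                              band[1], min(band[2], 2))
    if (any(!inband))
      x[!inband] <- rtruncnorm(sum(!inband), par[1], par[2], 0, 2)
    x
  }
  abi <- draw_index(vs("abi"), iss_index_bands("abi")[lev, ])
  tbi <- draw_index(vs("tbi"), iss_index_bands("tbi")[lev, ])
  tbi[stats::runif(n) < p$toe_unmeasurable_prob] <- NA_real_

  # raw pressures derived so that compute_abi / compute_tbi reproduce the
  # generated indices (HAP = ABI x max arm; second ankle pressure lower)
  ankle_hap <- abi * arm_max
  lower_frac <- stats::runif(n, 0.7, 1)
  dp_is_high <- stats::runif(n) < 0.5
  ankle_dp <- ifelse(dp_is_high, ankle_hap, ankle_hap * lower_frac)
  ankle_tp <- ifelse(dp_is_high, ankle_hap * lower_frac, ankle_hap)
  toe <- tbi * arm_max

  # palpation grades: latent level plus a +/-1 error, clamped to 0..3
  pulse_grade <- function() {
    e <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                prob = c(p$pulse_error_prob / 2, 1 - p$pulse_error_prob,
                         p$pulse_error_prob / 2))
    pmin(pmax(level + e, 0L), 3L)
  }
  pulse_dp <- pulse_grade()
  pulse_tp <- pulse_grade()

  wf_names <- names(scoring_config()$waveform_map)
  has_wf <- stats::runif(n) < p$waveform_present_prob[level + 1]
  wf_level <- ifelse(stats::runif(n) < p$band_concordance, level,
                     pmin(pmax(level + sample(c(-1L, 1L), n, replace = TRUE), 0L), 3L))
  waveform <- ifelse(has_wf, wf_names[wf_level + 1], NA_character_)

  # SEWSS: ischaemia factor equals the latent level; the other nine factors
  # absorb the rest of a score sum drawn from the level's summary
  ss <- bl("sewss_sum")
  target <- round(rtruncnorm(n, ss[1], ss[2], level, 27 + level))
  sub <- t(vapply(target - level, distribute_subscores, integer(9)))
  fac <- sewss_factor_names()
  subscores <- matrix(0L, n, 10, dimnames = list(NULL, fac))
  subscores[, setdiff(fac, "sewss_ischaemia")] <- sub
  subscores[, "sewss_ischaemia"] <- level

  outc <- colnames(p$outcome_probs)[
    sample.int(5, n, replace = TRUE, prob = p$outcome_probs[level + 1, ])]
  shape <- p$weibull_shape
  scale <- p$weibull_scale[level + 1]
  # truncated Weibull via inversion
  tw <- function(m) {
    lo <- stats::pweibull(p$time_range[1], shape, scale)
    hi <- stats::pweibull(p$time_range[2], shape, scale)
    stats::qweibull(stats::runif(m, lo, hi), shape, scale)
  }
  time <- tw(n)
  time[outc == "censored"] <- p$followup_weeks
  delayed_death <- stats::runif(n) < p$delayed_death_prob[level + 1]

  cbind(
    data.frame(true_level = rep(as.integer(level), n), age = age, sex = sex,
               diabetes_duration = duration, hba1c = hba1c,
               smoking = smoking, wound_history = history,
               wound_size = wound_size,
               arm_systolic_left = arm_l, arm_systolic_right = arm_r,
               ankle_systolic_dp = ankle_dp, ankle_systolic_tp = ankle_tp,
               toe_systolic = toe,
               pulse_dorsalis = pulse_dp, pulse_tibialis = pulse_tp,
               waveform = waveform, stringsAsFactors = FALSE),
    as.data.frame(subscores),
    data.frame(outcome = outc, time_to_event = time,
               delayed_death = delayed_death, stringsAsFactors = FALSE))
}

#' Generate one synthetic patient
#'
#' Draws a single patient record at the given latent ISS level from the
#' current RNG state.  \code{\link{generate_cohort}} is the seeded batch
#' interface.
#'
#' @param params a \code{\link{cohort_params}} object.
#' @param level latent ischaemia severity level, 0--3.
#' @return one-row data.frame in the cohort schema.
#' @export
generate_patient <- function(params, level) {
  if (!(length(level) == 1 && level %in% 0:3))
    stop_sewss("level must be a single value in 0..3")
  validate_cohort_params(params)
  rec <- generate_level_block(params, as.integer(level), 1L)
  rec$id <- 1L
  rec[, c("id", setdiff(names(rec), "id"))]
}

#' Generate a seeded synthetic cohort
#'
#' Draws \code{params$n} patient records.  In exact-count mode the per-level
#' counts are fixed (default 159/24/25/27); in multinomial mode each
#' patient's latent level is drawn from the level proportions.  The output
#' is byte-reproducible given the seed.
#'
#' @param params a \code{\link{cohort_params}} object.
#' @param seed integer seed; overrides \code{params$seed}.
#' @return data.frame, one row per patient, in the flat cohort schema
#'   (demographics, raw vascular measurements, ten SEWSS factor subscores,
#'   outcome and time-to-event).  The generator's latent level is kept in
#'   \code{true_level}.
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  validate_cohort_params(params)
  if (is.null(seed)) stop_sewss("a seed is required for cohort generation")
  set.seed(as.integer(seed))
  if (params$n == 0) {
    out <- generate_level_block(params, 0L, 0L)
    out$id <- integer(0)
    return(out[, c("id", setdiff(names(out), "id"))])
  }
  levels <- if (params$assignment == "exact") {
    rep(0:3, params$level_counts)
  } else {
    sample(0:3, params$n, replace = TRUE, prob = params$level_proportions)
  }
  blocks <- lapply(0:3, function(l) {
    m <- sum(levels == l)
    if (m > 0) generate_level_block(params, l, m) else NULL
  })
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  # restore presentation order for multinomial assignment
  ord <- order(order(levels))
  out <- out[ord, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("id", setdiff(names(out), "id"))]
}

#' Simulate a pair of independent raters
#'
#' Emulates two observers independently assigning ISS levels to the same
#' patients: each observer reports the true level with probability
#' \code{1 - miss_prob[level + 1]} and an adjacent level otherwise.
#' Interior levels can be missed in either direction, so their chance-corrected
#' agreement is naturally lower than at the scale ends, as reported for
#' pulse-palpation scoring in the validation study.
#'
#' @param true_levels integer vector of latent levels 0--3.
#' @param miss_prob per-level probability that an observer misgrades by one.
#' @return data.frame with columns \code{rater_a}, \code{rater_b}.
#' @export
simulate_raters <- function(true_levels,
                            miss_prob = c(0.05, 0.20, 0.20, 0.05)) {
  stopifnot(all(true_levels %in% 0:3))
  n <- length(true_levels)
  one <- function() {
    miss <- stats::runif(n) < miss_prob[true_levels + 1]
    dir <- sample(c(-1L, 1L), n, replace = TRUE)
    pmin(pmax(true_levels + ifelse(miss, dir, 0L), 0L), 3L)
  }
  data.frame(rater_a = one(), rater_b = one())
}
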