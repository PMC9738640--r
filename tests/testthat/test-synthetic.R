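test_that("cohort generation is deterministic under a fixed seed", {
  p <- cohort_params(seed = 11L)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  c3 <- generate_cohort(p, seed = 12L)
  expect_false(identical(c1, c3))
})

test_that("exact-count mode reproduces the 159/24/25/27 composition", {
  co <- generate_cohort(cohort_params(), seed = 5)
  expect_equal(nrow(co), 235L)
  expect_equal(as.integer(table(factor(co$true_level, levels = 0:3))),
               c(159L, 24L, 25L, 27L))
})

test_that("an empty cohort is a zero-row table in the schema", {
  p <- cohort_params(n = 0L, level_counts = c(0L, 0L, 0L, 0L))
  co <- generate_cohort(p, seed = 1)
  expect_equal(nrow(co), 0L)
  expect_true(all(cohort_schema()$required %in%
                  c(names(co), "id")))
})

test_that("records satisfy the physical and follow-up invariants", {
  co <- generate_cohort(cohort_params(seed = 3L))
  expect_true(all(co$wound_size > 0))
  expect_true(all(co$time_to_event > 0 & co$time_to_event <= 52))
  expect_true(all(co$arm_systolic_left > 0 & co$arm_systolic_right > 0))
  expect_true(all(co$toe_systolic >= 0, na.rm = TRUE))
  expect_true(all(co$pulse_dorsalis %in% 0:3 & co$pulse_tibialis %in% 0:3))
  sub <- as.matrix(co[, sewss_factor_names()])
  expect_true(all(sub %in% 0:3))
  expect_equal(co$sewss_ischaemia, co$true_level)
  expect_true(all(co$outcome %in% c("healed", "major_amputation", "abandoned",
                                    "early_death", "censored")))
})

test_that("degenerate zero-SD parameters reproduce the level means exactly", {
  p <- cohort_params(n = 8L, level_counts = c(8L, 0L, 0L, 0L), seed = 9L)
  p$baseline[, c("sd0", "sd1", "sd2", "sd3")] <- 0
  p$vascular[, c("sd0", "sd1", "sd2", "sd3")] <- 0
  p$band_concordance <- 1
  co <- generate_cohort(p, seed = 9L)
  expect_true(all(co$age == p$baseline$mean0[p$baseline$variable == "age"]))
  expect_true(all(co$hba1c == p$baseline$mean0[p$baseline$variable == "hba1c"]))
  abi <- compute_abi(co$ankle_systolic_dp, co$ankle_systolic_tp,
                     co$arm_systolic_left, co$arm_systolic_right)$abi
  expect_equal(abi, rep(1.1, 8), tolerance = 1e-12)
})

test_that("scored ISS recovers the latent level for a large majority", {
  co <- generate_cohort(cohort_params(n = 2000L,
                                      level_counts = c(1352L, 204L, 213L, 231L),
                                      seed = 21L))
  sc <- score_cohort(co)
  expect_gt(mean(sc$iss == sc$true_level), 0.90)
})

test_that("multinomial assignment concentrates on the level proportions", {
  p <- cohort_params(n = 4000L, assignment = "multinomial", seed = 13L)
  co <- generate_cohort(p)
  share0 <- mean(co$true_level == 0)
  p0 <- p$level_proportions[1]
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(share0 - p0), 3 * se)
})

test_that("per-level outcome frequencies recover the generating probabilities", {
  p <- cohort_params(n = 4000L, assignment = "multinomial", seed = 17L)
  co <- generate_cohort(p)
  for (l in 0:3) {
    sub <- co[co$true_level == l, ]
    for (oc in c("healed", "major_amputation", "abandoned")) {
      pr <- p$outcome_probs[l + 1, oc]
      obs <- mean(sub$outcome == oc)
      se <- sqrt(pr * (1 - pr) / nrow(sub))
      expect_lt(abs(obs - pr), 3 * se + 1e-9)
    }
  }
})

test_that("index sample means match the truncated-mixture generating means", {
  p <- cohort_params(n = 6000L,
                     level_counts = c(6000L, 0L, 0L, 0L), seed = 19L)
  co <- generate_cohort(p)
  # closed-form mean of the band/off-band truncated normal mixture
  tn_mean <- function(m, s, lo, hi) {
    a <- (lo - m) / s; b <- (hi - m) / s
    m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  gen_mean <- p$band_concordance * tn_mean(1.1, 0.1, 0.9, 1.2) +
    (1 - p$band_concordance) * tn_mean(1.1, 0.1, 0, 2)
  sc <- score_cohort(co)
  se <- sd(sc$abi) / sqrt(nrow(co))
  expect_lt(abs(mean(sc$abi) - gen_mean), 3 * se)
})

test_that("generate_patient draws one record at the requested level", {
  p <- cohort_params(seed = 1L)
  set.seed(4)
  rec <- generate_patient(p, 3)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$true_level, 3L)
  expect_error(generate_patient(p, 5), "level")
})

test_that("simulated rater pairs agree more at the scale ends", {
  set.seed(31)
  lev <- sample(0:3, 6000, replace = TRUE,
                prob = c(159, 24, 25, 27) / 235)
  r <- simulate_raters(lev)
  k <- per_level_dichotomous_kappa(r$rater_a, r$rater_b)
  expect_gt(k["level_0"], k["level_1"])
  expect_gt(k["level_3"], k["level_2"])
  expect_true(all(k > 0.3))
})
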