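test_that("ABI uses the high ankle pressure over the maximum arm pressure", {
  r <- compute_abi(120, 100, 100, 95)
  expect_equal(r$abi, 1.20)
  expect_false(r$incompressible)
  expect_equal(compute_abi(55, 47, 100, 110)$abi, 0.50)
  r <- compute_abi(150, 140, 100, 100)
  expect_equal(r$abi, 1.50)
  expect_true(r$incompressible)
  # single ankle measurement is enough
  expect_equal(compute_abi(NA, 90, 100, 100)$abi, 0.90)
  expect_error(compute_abi(NA, NA, 100, 100), "no ankle measurement")
  expect_error(compute_abi(120, 100, 0, 95), "arm")
  expect_error(compute_abi(120, 100, NA, 95), "arm")
})

test_that("TBI divides toe pressure by the maximum arm pressure", {
  expect_equal(compute_tbi(90, 100, 95), 0.90)
  expect_equal(compute_tbi(0, 100, 100), 0.00)
  expect_equal(compute_tbi(26.5, 100, 100), 0.265)
  expect_true(is.na(compute_tbi(NA, 100, 100)))  # recorded, not fatal
  expect_error(compute_tbi(-5, 100, 100), "non-negative")
})

test_that("pulse palpation scores the worse of the two foot arteries", {
  expect_equal(iss_from_pulse(0, 0)$level, 0L)
  expect_equal(iss_from_pulse(3, 3)$level, 3L)
  expect_equal(iss_from_pulse(1, 2)$level, 2L)
  expect_equal(iss_from_pulse(2, NA)$level, 2L)
  expect_equal(iss_from_pulse(0, 0)$decided_by, "pulse")
  expect_error(iss_from_pulse(NA, NA), "no pulse assessment")
  expect_error(iss_from_pulse(4, 0), "0..3")
})

test_that("ABI bands classify the published per-level means to their levels", {
  expect_equal(iss_from_abi(c(1.1, 0.86, 0.68, 0.47))$level, 0:3)
  expect_equal(iss_from_abi(0.895)$level, 1L)
  expect_true(is.na(iss_from_abi(1.30)$level))  # incompressible: defer
  expect_equal(iss_from_abi(1.1)$label, "non-ischaemic")
  expect_error(iss_from_abi(-0.1), "non-negative")
})

test_that("TBI bands classify the published per-level means to their levels", {
  expect_equal(iss_from_tbi(c(0.90, 0.62, 0.50, 0.10))$level, 0:3)
  expect_equal(iss_from_tbi(0.60)$level, 1L)  # closed lower bound of mild
  expect_equal(iss_from_tbi(0.75)$level, 0L)  # >= 0.75 normal
  expect_error(iss_from_tbi(-0.2), "non-negative")
})

test_that("waveform categories map triphasic/biphasic/monophasic/absent to 0-3", {
  expect_equal(iss_from_waveform(c("triphasic", "biphasic", "monophasic",
                                   "absent"))$level, 0:3)
  expect_error(iss_from_waveform("sinusoidal"), "unknown waveform")
})

test_that("index bands partition the non-negative axis and are monotone", {
  grid <- seq(0, 1.5, by = 0.0005)
  abi_lev <- iss_from_abi(grid)$level
  classifiable <- grid <= 1.2
  expect_true(all(!is.na(abi_lev[classifiable])))
  expect_true(all(is.na(abi_lev[!classifiable])))
  # lower ABI never yields a lower severity level
  expect_true(all(diff(abi_lev[classifiable]) <= 0))
  tbi_lev <- iss_from_tbi(grid)$level
  expect_true(all(!is.na(tbi_lev)))
  expect_true(all(diff(tbi_lev) <= 0))
})

test_that("resolve_iss applies the waveform > TBI > ABI > pulse precedence", {
  a <- data.frame(pulse_dorsalis = 0, pulse_tibialis = 0, abi = 1.1,
                  tbi = 0.90, waveform = NA)
  r <- resolve_iss(a)
  expect_equal(r$level, 0L)
  expect_equal(r$decided_by, "tbi")

  r <- resolve_iss(data.frame(abi = 0.86, tbi = 0.50, waveform = NA,
                              pulse_dorsalis = NA))
  expect_equal(r$level, 2L)
  expect_equal(r$decided_by, "tbi")

  # incompressible ABI is skipped, not classified
  r <- resolve_iss(data.frame(abi = 1.30, tbi = 0.20))
  expect_equal(r$level, 3L)
  expect_equal(r$decided_by, "tbi")

  # waveform outranks everything when present
  r <- resolve_iss(data.frame(abi = 1.1, tbi = 0.9, waveform = "monophasic"))
  expect_equal(r$level, 2L)
  expect_equal(r$decided_by, "waveform")

  expect_error(resolve_iss(data.frame(abi = 1.4, tbi = NA_real_)),
               "unassessable")
})

test_that("resolve_iss ignores lower-precedence tests once a higher one decides", {
  base <- data.frame(tbi = 0.45)
  with_lower <- data.frame(tbi = 0.45, abi = 1.05, pulse_dorsalis = 0,
                           pulse_tibialis = 1)
  expect_equal(resolve_iss(base)$level, resolve_iss(with_lower)$level)
  # idempotence: rescoring the scored assessment changes nothing
  r1 <- resolve_iss(with_lower)
  r2 <- resolve_iss(with_lower)
  expect_identical(r1, r2)
})

test_that("resolve_iss derives indices from raw pressures when needed", {
  a <- data.frame(ankle_systolic_dp = 55, ankle_systolic_tp = 47,
                  arm_systolic_left = 100, arm_systolic_right = 110,
                  toe_systolic = NA, waveform = NA)
  r <- resolve_iss(a)
  expect_equal(r$level, 2L)       # ABI 55/110 = 0.50, moderate band
  expect_equal(r$decided_by, "abi")
})

test_that("SEWSS sums and grade bands follow the 10/20/30 cut points", {
  r <- sewss_sum_and_grade(rep(1, 10))
  expect_equal(r$score_sum, 10L)
  expect_equal(as.character(r$grade), "I")
  r <- sewss_sum_and_grade(c(rep(2, 5), rep(1, 5)))   # sum 15
  expect_equal(as.character(r$grade), "II")
  r <- sewss_sum_and_grade(c(rep(3, 7), 0, 0, 0))     # sum 21
  expect_equal(as.character(r$grade), "III")
  expect_error(sewss_sum_and_grade(c(rep(1, 9), 4)), "0..3")
  expect_error(sewss_sum_and_grade(rep(1, 9)), "ten")
})

test_that("SEWSS grade agrees with exhaustive enumeration over sums 0-30", {
  for (s in 0:30) {
    # build ten subscores summing to s
    sub <- rep(3, s %/% 3)
    if (s %% 3 > 0) sub <- c(sub, s %% 3)
    sub <- c(sub, rep(0, 10 - length(sub)))
    g <- as.character(sewss_sum_and_grade(sub)$grade)
    expect_equal(g, if (s <= 10) "I" else if (s <= 20) "II" else "III")
  }
  # grade is monotone non-decreasing in the score sum
  grades <- vapply(0:30, function(s) {
    sub <- c(rep(3, s %/% 3), if (s %% 3) s %% 3, rep(0, 10))[1:10]
    as.integer(sewss_sum_and_grade(sub)$grade)
  }, integer(1))
  expect_true(all(diff(grades) >= 0))
})
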