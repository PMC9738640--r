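test_that("crosstab counts co-occurrences with ordered labels", {
  co <- data.frame(iss = 0:3, outcome = "healed")
  tab <- crosstab(co, "iss", "outcome")
  expect_equal(dim(tab), c(4L, 1L))
  expect_true(all(tab == 1))
  expect_error(crosstab(co, "iss", "nope"), "unknown variable")
  empty <- crosstab(co[0, ], "iss", "outcome")
  expect_true(isTRUE(attr(empty, "degenerate")))
})

test_that("rate tables reproduce the published column percentages", {
  totals <- c(159, 24, 25, 27)
  dorsalis <- matrix(c(112, 12, 2, 0), 1)
  expect_equal(as.numeric(rate_table(dorsalis, totals)),
               c(70.4, 50.0, 8.0, 0.0))
  amput <- matrix(c(7, 3, 4, 19), 1)
  expect_equal(as.numeric(rate_table(amput, totals)),
               c(4.4, 12.5, 16.0, 70.4))
  expect_equal(as.numeric(rate_table(matrix(5), 5)), 100.0)
  # zero column total reports missing, not zero
  z <- rate_table(matrix(c(3, 0), 1), c(10, 0))
  expect_true(is.na(z[1, 2]))
})

test_that("exhaustive rate-table rows sum to 100 within rounding", {
  set.seed(10)
  for (i in 1:30) {
    counts <- matrix(rpois(12, 20), 3, 4)
    pct <- rate_table(counts)
    expect_true(all(abs(colSums(pct) - 100) <= 0.2))
  }
})

test_that("odds ratios follow ad/bc with the Woolf interval", {
  r <- odds_ratio(10, 10, 5, 20)
  expect_equal(r$or, 4.0)
  r <- odds_ratio(7, 7, 7, 7)
  expect_equal(r$or, 1.0)
  expect_true(r$ci_low < 1 && r$ci_high > 1)
  # severe vs non-ischaemic major amputation from the published counts
  r <- odds_ratio(19, 8, 7, 152)
  expect_equal(r$or, 51.571, tolerance = 1e-3)
  expect_error(odds_ratio(0, 0, 5, 5), "undefined")
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  r <- odds_ratio(0, 24, 3, 156)
  expect_true(r$corrected)
  expect_equal(r$or, (0.5 * 156.5) / (24.5 * 3.5))
  expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
})

test_that("odds ratio has reciprocal symmetry without correction", {
  set.seed(11)
  for (i in 1:100) {
    cells <- rpois(4, 10) + 1
    r1 <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    r2 <- odds_ratio(cells[2], cells[1], cells[4], cells[3])
    expect_equal(r1$or * r2$or, 1, tolerance = 1e-12)
  }
})

test_that("OR and CI agree with a saturated logistic fit", {
  set.seed(12)
  for (i in 1:100) {
    cells <- rpois(4, 12) + 1
    mine <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    orc <- oracle_or_glm(cells[1], cells[2], cells[3], cells[4])
    expect_equal(unname(c(mine$or, mine$ci_low, mine$ci_high)),
                 unname(orc), tolerance = 1e-7)
  }
})

test_that("trend statistic equals (n-1) r^2 on the expanded data", {
  t1 <- mh_trend_test(c(10, 10, 10), c(30, 30, 30))
  expect_lt(unname(t1$statistic), 1e-10)
  t2 <- mh_trend_test(c(0, 10, 20), c(10, 20, 30))
  expect_equal(unname(t2$statistic), oracle_trend(c(0, 10, 20), c(10, 20, 30)),
               tolerance = 1e-12)
  # all outcomes identical: statistic 0, p = 1
  t3 <- mh_trend_test(c(0, 0, 0), c(5, 5, 5))
  expect_equal(unname(t3$statistic), 0)
  expect_equal(t3$p.value, 1)
})

test_that("trend statistic is invariant to affine score transformations", {
  ev <- c(3, 8, 14, 20); tot <- c(40, 30, 30, 30)
  s1 <- mh_trend_test(ev, tot, scores = 0:3)$statistic
  s2 <- mh_trend_test(ev, tot, scores = 10 + 5 * (0:3))$statistic
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
})

test_that("Kruskal-Wallis handles ties and degenerate input", {
  r <- kruskal_wallis(list(c(2, 2, 2), c(2, 2), c(2, 2, 2)))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  # completely separated ranks, n = 6: H from hand-ranked computation
  g <- list(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(kruskal_wallis(g)$statistic), oracle_kw(g),
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Kruskal-Wallis agrees with the rank-formula oracle", {
  set.seed(13)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:8, sample(3:10, 1), replace = TRUE))  # heavy ties
    expect_equal(unname(kruskal_wallis(groups)$statistic),
                 oracle_kw(groups), tolerance = 1e-10)
  }
})

test_that("or_ladder compares each level against the reference", {
  lad <- or_ladder(c(7, 3, 4, 19), c(159, 24, 25, 27), "major_amputation")
  expect_equal(nrow(lad), 3L)
  expect_equal(lad$level, 1:3)
  expect_equal(lad$or[3], 51.571, tolerance = 1e-3)
  expect_true(all(diff(lad$or) > 0))
})
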