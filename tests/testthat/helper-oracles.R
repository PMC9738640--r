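# Independent oracle implementations used to cross-check the package's
# statistics.  They deliberately take different computational routes
# (reference packages, brute-force expansion, grid maximisation).

oracle_kappa <- function(tab) e1071::classAgreement(tab)$kappa

# tie-corrected Kruskal-Wallis H from first principles
oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else H / corr
}

# trend statistic by brute-force expansion to individual 0/1 observations
oracle_trend <- function(events, totals, scores = seq_along(events) - 1) {
  y <- unlist(mapply(function(e, t) c(rep(1, e), rep(0, t - e)),
                     events, totals, SIMPLIFY = FALSE))
  x <- rep(scores, totals)
  n <- length(y)
  (n - 1) * stats::cor(x, y)^2
}

# odds ratio and Woolf CI recomputed on the log scale (independent algebra:
# log-cell sums rather than a ratio of products)
oracle_or_closed <- function(a, b, c, d, conf_level = 0.95) {
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(or = exp(lor), ci_low = exp(lor - z * se), ci_high = exp(lor + z * se))
}

# odds ratio and Woolf CI through a saturated logistic fit
oracle_or_glm <- function(a, b, c, d, conf_level = 0.95) {
  fit <- suppressWarnings(
    stats::glm(cbind(c(a, c), c(b, d)) ~ c(1, 0), family = stats::binomial,
               control = stats::glm.control(epsilon = 1e-14, maxit = 100)))
  est <- stats::coef(fit)[2]
  se <- sqrt(diag(stats::vcov(fit)))[2]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se))
}

oracle_km <- function(time, event) {
  f <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = f$time, surv = f$surv)
}

oracle_logrank <- function(time, event, group) {
  survival::survdiff(survival::Surv(time, event) ~ group)$chisq
}

oracle_cox_coef <- function(time, event, x) {
  f <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 100)))
  unname(stats::coef(f))
}

# grid/1-d maximisation of the Breslow partial likelihood for one covariate
oracle_cox_grid <- function(time, event, x, interval = c(-5, 5)) {
  pl <- function(beta) {
    eta <- beta * x
    w <- exp(eta)
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      risk <- time >= t
      dead <- time == t & event == 1
      ll <- ll + sum(eta[dead]) - sum(dead) * log(sum(w[risk]))
    }
    ll
  }
  stats::optimize(pl, interval, maximum = TRUE, tol = 1e-10)$maximum
}

# random small survival dataset with ties
random_surv <- function(n = 20, k = 2) {
  list(time = sample(1:12, n, replace = TRUE),
       event = stats::rbinom(n, 1, 0.7),
       group = sample(seq_len(k), n, replace = TRUE))
}
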