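#' Kaplan--Meier product-limit estimator
#'
#' Estimates the time-to-healing curve for one group.  The "event" is wound
#' healing; amputation, abandonment, death and end of follow-up are
#' right-censored.  Censorings tied with events at the same time are counted
#' at risk for that time (tie-broken after the events), the standard
#' product-limit convention.
#'
#' @param time positive event/censoring times (weeks).
#' @param event 1 = healed (event), 0 = censored.
#' @return object of class \code{sewss_km}: data.frame with \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv} at each
#'   distinct observed time; \code{S(0) = 1} implicitly.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop_sewss("no observations")
  if (any(is.na(time)) || any(time <= 0))
    stop_sewss("times must be positive")
  event <- as.integer(event)
  stopifnot(length(event) == length(time), all(event %in% 0:1))
  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("sewss_km", "data.frame"))
}

#' Evaluate a Kaplan--Meier curve
#'
#' Step-function value of the estimated survival at arbitrary times.
#'
#' @param km a \code{\link{km_estimate}} result.
#' @param t times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i) == 0) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Kaplan--Meier curves by ISS level
#'
#' @param time,event as in \code{\link{km_estimate}}.
#' @param group grouping vector (ISS levels).
#' @return named list of \code{sewss_km} curves, class \code{sewss_km_list}.
#' @export
km_by_group <- function(time, event, group) {
  g <- sort(unique(group))
  out <- lapply(g, function(l) km_estimate(time[group == l], event[group == l]))
  names(out) <- as.character(g)
  structure(out, class = "sewss_km_list")
}

#' @export
plot.sewss_km_list <- function(x, col = seq_along(x), lty = 1,
                               xlab = "weeks", ylab = "healing-free proportion",
                               main = "Kaplan-Meier by ischaemia severity", ...) {
  xmax <- max(vapply(x, function(k) max(k$time), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  col <- rep_len(col, length(x)); lty <- rep_len(lty, length(x))
  for (i in seq_along(x)) {
    k <- x[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$surv)), col = col[i],
                    lty = lty[i], do.points = FALSE)
  }
  graphics::legend("topright", legend = names(x), col = col, lty = lty,
                   title = "ISS level", bty = "n")
  invisible(x)
}

#' k-group log-rank test
#'
#' Compares survival across 2--4 groups with the log-rank chi-square:
#' observed minus hypergeometric-expected events accumulated over the
#' distinct event times, with the hypergeometric variance-covariance, on
#' k - 1 degrees of freedom.
#'
#' @param time positive times.
#' @param event 1 = event, 0 = censored.
#' @param group grouping vector.
#' @return object of class \code{htest} with the chi-square statistic, df
#'   and p-value; the per-group observed and expected event counts are
#'   attached as \code{observed} and \code{expected}.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.integer(event)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop_sewss("times must be positive")
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2) stop_sewss("need at least two non-empty groups")
  if (sum(event) == 0) stop_sewss("log-rank undefined: no events")
  tt <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  gi <- as.integer(g)
  for (t in tt) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    dj <- sum(time == t & event == 1)
    ngj <- tabulate(gi[at_risk], nbins = k)
    dgj <- tabulate(gi[time == t & event == 1], nbins = k)
    O <- O + dgj
    E <- E + ngj * dj / nj
    if (nj > 1) {
      f <- dj * (nj - dj) / (nj^2 * (nj - 1))
      V <- V - f * tcrossprod(ngj)
      diag(V) <- diag(V) + f * ngj * nj
    }
  }
  i <- seq_len(k - 1)
  d <- (O - E)[i]
  stat <- tryCatch(drop(t(d) %*% solve(V[i, i, drop = FALSE], d)),
                   error = function(e)
                     drop(t(d) %*% MASS_ginv(V[i, i, drop = FALSE]) %*% d))
  pval <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  out <- structure(list(statistic = c(`log-rank chi-squared` = stat),
                        parameter = c(df = k - 1), p.value = pval,
                        method = "k-group log-rank test",
                        data.name = "time, event by group",
                        observed = stats::setNames(O, levels(g)),
                        expected = stats::setNames(E, levels(g))),
                   class = "htest")
  out
}

# Moore-Penrose pseudo-inverse via SVD (fallback for singular log-rank
# covariance, e.g. a group with no subjects at risk at any event time)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood with Breslow tie handling by
#' Newton--Raphson with step-halving.  Used to express the healing hazard of
#' each ischaemia level against a reference level.
#'
#' @param time positive times.
#' @param event 1 = event, 0 = censored.
#' @param covariates numeric vector/matrix of covariates, or a factor (the
#'   first factor level is the reference and indicator columns are built for
#'   the rest).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence threshold on the coefficient update norm.
#' @return object of class \code{sewss_cox} with \code{coef}, \code{se},
#'   \code{hr}, \code{ci_low}, \code{ci_high} (95% Wald), \code{loglik}
#'   (null and fitted), \code{iter}, \code{gradient}, and a
#'   \code{separation} flag for monotone likelihoods.
#' @export
cox_fit <- function(time, event, covariates, max_iter = 50, tol = 1e-9) {
  event <- as.integer(event)
  if (any(time <= 0)) stop_sewss("times must be positive")
  if (sum(event) == 0) stop_sewss("no events: Cox fit undefined")
  if (is.factor(covariates) || is.character(covariates)) {
    f <- factor(covariates)
    if (nlevels(f) < 2) stop_sewss("need at least two covariate values")
    X <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(X) <- paste0("level_", levels(f)[-1])
  } else {
    X <- as.matrix(covariates)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != length(time)) stop_sewss("covariate length mismatch")
  if (any(apply(X, 2, function(c) length(unique(c)) == 1)))
    stop_sewss("constant covariate column")
  p <- ncol(X)
  beta <- rep(0, p)

  loglik_parts <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    ll <- 0; U <- rep(0, p); I <- matrix(0, p, p)
    for (t in sort(unique(time[event == 1]))) {
      risk <- time >= t
      dead <- time == t & event == 1
      d <- sum(dead)
      s0 <- sum(w[risk])
      s1 <- drop(crossprod(X[risk, , drop = FALSE], w[risk]))
      s2 <- crossprod(X[risk, , drop = FALSE] * w[risk], X[risk, , drop = FALSE])
      ll <- ll + sum(eta[dead]) - d * log(s0)
      U <- U + colSums(X[dead, , drop = FALSE]) - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1 / s0))
    }
    list(ll = ll, U = U, I = I)
  }

  cur <- loglik_parts(beta)
  ll0 <- cur$ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(cur$I, cur$U), error = function(e)
      stop_sewss("singular information matrix in Cox fit"))
    # step-halving if the likelihood does not improve
    h <- 1
    repeat {
      cand <- beta + h * step
      new <- loglik_parts(cand)
      if (new$ll >= cur$ll - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    delta <- sqrt(sum((h * step)^2))
    beta <- cand
    cur <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_sewss("Cox fit did not converge after ", max_iter,
               " iterations (last update ", format(delta), ")")
  separation <- any(abs(beta) > 15)
  se <- sqrt(diag(solve(cur$I)))
  z <- stats::qnorm(0.975)
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = exp(beta), ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se),
                 loglik = c(null = ll0, fitted = cur$ll),
                 iter = iter, gradient = cur$U,
                 separation = separation),
            class = "sewss_cox")
}

#' @export
print.sewss_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  tab <- data.frame(coef = x$coef, se = x$se, HR = x$hr,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, 4))
  cat(sprintf("loglik: null %.4f -> fitted %.4f; %d Newton iterations\n",
              x$loglik[1], x$loglik[2], x$iter))
  if (x$separation)
    cat("warning: coefficient magnitude suggests monotone likelihood\n")
  invisible(x)
}

#' Healing-hazard ratios of ISS levels against a reference level
#'
#' Convenience wrapper fitting \code{\link{cox_fit}} with indicator
#' covariates for every ISS level against the chosen reference (default the
#' severe level 3, so reported hazard ratios say how much faster milder
#' levels heal).
#'
#' @param time,event as in \code{\link{cox_fit}}.
#' @param level ISS levels 0--3.
#' @param reference reference level.
#' @return \code{sewss_cox} object.
#' @export
cox_by_level <- function(time, event, level, reference = 3) {
  lv <- sort(unique(level))
  f <- factor(level, levels = c(reference, setdiff(lv, reference)))
  cox_fit(time, event, f)
}
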