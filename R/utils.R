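#' Round half away from zero
#'
#' Decimal rounding with ties going up (round-half-up), the convention used
#' when printing clinical rate tables.  Base \code{round()} rounds half to
#' even, which disagrees on values such as 12.45.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# one draw per element from N(mean, sd) truncated to [lower, upper]
# by inversion; sd = 0 degenerates to the mean (clamped into range).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(all(sd >= 0), all(lower <= upper))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  out <- numeric(n)
  deg <- sd == 0
  out[deg] <- pmin(pmax(mean[deg], lower[deg]), upper[deg])
  if (any(!deg)) {
    i <- !deg
    plo <- stats::pnorm(lower[i], mean[i], sd[i])
    phi <- stats::pnorm(upper[i], mean[i], sd[i])
    u <- stats::runif(sum(i), plo, phi)
    out[i] <- stats::qnorm(u, mean[i], sd[i])
    # guard against qnorm(1) = Inf from extreme truncation
    out[i] <- pmin(pmax(out[i], lower[i]), upper[i])
  }
  out
}

stop_sewss <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
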