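#' Cohen's kappa for a square contingency table
#'
#' Chance-corrected inter-rater agreement: K = (Po - Pe) / (1 - Pe), with
#' Po the observed agreement (diagonal proportion) and Pe the agreement
#' expected under independent raters with the observed marginals.
#'
#' @param counts square matrix of cross-tabulated ratings (rows = rater A,
#'   columns = rater B), non-negative counts.
#' @return list of class \code{sewss_kappa} with \code{kappa}, \code{po},
#'   \code{pe} and \code{n}.
#' @examples
#' cohen_kappa(matrix(c(40, 5, 10, 45), 2))  # kappa = 0.70
#' @export
cohen_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop_sewss("kappa needs a square table")
  if (any(counts < 0) || any(is.na(counts)))
    stop_sewss("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop_sewss("empty table")
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (1 - pe <= .Machine$double.eps * 4)
    stop_sewss("kappa undefined: degenerate marginals (Pe = 1)")
  structure(list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, n = n),
            class = "sewss_kappa")
}

#' @export
print.sewss_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f  (Po = %.4f, Pe = %.4f, n = %d)\n",
              x$kappa, x$po, x$pe, x$n))
  invisible(x)
}

#' Per-level dichotomised kappa
#'
#' For each ISS level L, collapses two observers' 0--3 ratings to the 2x2
#' "is level L" vs "is not level L" table and returns that table's Cohen
#' kappa, mirroring how per-level agreement is reported for ordinal clinical
#' scales.
#'
#' @param ratings_a,ratings_b equal-length integer vectors of levels 0--3.
#' @param levels the levels to dichotomise on.
#' @return named numeric vector of kappas, one per level (\code{NA} when a
#'   level's 2x2 table is degenerate).
#' @export
per_level_dichotomous_kappa <- function(ratings_a, ratings_b, levels = 0:3) {
  if (length(ratings_a) != length(ratings_b))
    stop_sewss("rating vectors must have equal length")
  if (length(ratings_a) == 0) stop_sewss("empty rating vectors")
  if (any(is.na(c(ratings_a, ratings_b))))
    stop_sewss("ratings must be complete")
  out <- vapply(levels, function(l) {
    a <- factor(ratings_a == l, levels = c(TRUE, FALSE))
    b <- factor(ratings_b == l, levels = c(TRUE, FALSE))
    tab <- table(a, b)
    k <- tryCatch(cohen_kappa(tab)$kappa, error = function(e) NA_real_)
    k
  }, numeric(1))
  names(out) <- paste0("level_", levels)
  out
}
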