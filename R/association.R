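#' Cross-tabulate two cohort variables
#'
#' Counts co-occurrences of two categorical variables on the cohort.  ISS
#' levels are kept in ascending order; other labels sort naturally.
#'
#' @param cohort cohort data.frame.
#' @param row_var,col_var column names of categorical variables.
#' @return integer matrix of counts with named dimnames.  An all-zero table
#'   (empty cohort) carries attribute \code{degenerate = TRUE}.
#' @export
crosstab <- function(cohort, row_var, col_var) {
  for (v in c(row_var, col_var))
    if (!v %in% names(cohort)) stop_sewss("unknown variable: ", v)
  tab <- table(cohort[[row_var]], cohort[[col_var]], useNA = "no")
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c(row_var, col_var)
  if (sum(m) == 0) attr(m, "degenerate") <- TRUE
  m
}

#' Column-percentage rate table
#'
#' Converts a count table into per-column percentages, the format of the
#' published per-level summary tables: percent = 100 * cell / column total,
#' rounded half-up to one decimal.  Columns with a zero total report
#' \code{NA}, not 0.
#'
#' @param counts matrix of non-negative counts.
#' @param col_totals optional column totals; defaults to the column sums.
#'   Supply these when rows are non-exhaustive (e.g. "palpable pulse"
#'   indicator rows over the full per-level n).
#' @param digits decimals to keep (round half-up).
#' @return numeric matrix of percentages, same shape as \code{counts}.
#' @export
rate_table <- function(counts, col_totals = colSums(counts), digits = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_sewss("counts must be non-negative")
  if (length(col_totals) != ncol(counts))
    stop_sewss("col_totals length must match the number of columns")
  pct <- sweep(counts, 2, col_totals, "/") * 100
  pct[, col_totals == 0] <- NA_real_
  round_half_up(pct, digits)
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with cells a (exposed, event), b (exposed, no event),
#' c (unexposed, event), d (unexposed, no event): OR = ad / bc with the 95%
#' CI from Woolf's log method, exp(log OR +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d)).  When any cell is zero the Haldane--Anscombe correction adds 0.5
#' to every cell.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf_level confidence level (default 0.95).
#' @param outcome_name,comparison_level optional labels carried through to
#'   the result.
#' @return list of class \code{sewss_or} with \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{corrected} (whether the 0.5 correction fired) and
#'   the labels.
#' @examples
#' odds_ratio(10, 10, 5, 20)  # OR = 4
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95,
                       outcome_name = NULL, comparison_level = NULL) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(is.na(cells)))
    stop_sewss("cell counts must be non-negative")
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop_sewss("OR undefined: a zero row or column margin")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 conf_level = conf_level, corrected = corrected,
                 outcome_name = outcome_name,
                 comparison_level = comparison_level),
            class = "sewss_or")
}

#' @export
print.sewss_or <- function(x, ...) {
  lbl <- if (!is.null(x$outcome_name)) paste0(x$outcome_name, ": ") else ""
  cat(sprintf("%sOR = %.2f [%.0f%% CI %.2f-%.2f]%s\n", lbl, x$or,
              100 * x$conf_level, x$ci_low, x$ci_high,
              if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Odds-ratio ladder against the non-ischaemic reference
#'
#' For a 2 x k outcome-by-level count layout, computes the odds ratio of the
#' outcome at each level 1..k-1 against the reference level (first column).
#'
#' @param events integer vector of outcome counts per level (reference
#'   first).
#' @param totals per-level totals.
#' @param outcome_name label carried to the results.
#' @param conf_level confidence level.
#' @return data.frame with one row per comparison level.
#' @export
or_ladder <- function(events, totals, outcome_name = "outcome",
                      conf_level = 0.95) {
  stopifnot(length(events) == length(totals), all(events <= totals))
  k <- length(events)
  ref_e <- events[1]; ref_t <- totals[1]
  rows <- lapply(2:k, function(i) {
    r <- tryCatch(
      odds_ratio(events[i], totals[i] - events[i],
                 ref_e, ref_t - ref_e, conf_level,
                 outcome_name = outcome_name, comparison_level = i - 1),
      error = function(e) list(or = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, corrected = NA))
    data.frame(outcome = outcome_name, level = i - 1, or = r$or,
               ci_low = r$ci_low, ci_high = r$ci_high,
               corrected = r$corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mantel--Haenszel chi-square test for linear trend
#'
#' Tests for a linear trend in a binary outcome across ordered categories
#' using the statistic (n - 1) r^2, where r is the Pearson correlation
#' between the 0/1 outcome and the category scores over the individual
#' observations; referred to chi-square with 1 degree of freedom.
#'
#' @param events successes per ordered category.
#' @param totals observations per category.
#' @param scores numeric scores for the categories (default equally spaced
#'   starting at 0).
#' @return object of class \code{htest}.
#' @export
mh_trend_test <- function(events, totals, scores = seq_along(events) - 1) {
  stopifnot(length(events) == length(totals),
            length(scores) == length(events),
            all(events >= 0), all(events <= totals))
  if (length(events) < 2) stop_sewss("need at least two ordered categories")
  n <- sum(totals)
  if (n < 2) stop_sewss("need at least two observations")
  p <- sum(events) / n
  if (p == 0 || p == 1) {
    stat <- 0; pval <- 1
  } else {
    # moments of (outcome, score) over the expanded individual data
    xbar <- sum(scores * totals) / n
    sxx <- sum(scores^2 * totals) / n - xbar^2
    sxy <- sum(scores * events) / n - xbar * p
    syy <- p * (1 - p)
    if (sxx == 0) stop_sewss("scores are constant")
    r2 <- sxy^2 / (sxx * syy)
    stat <- (n - 1) * r2
    pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = c(`MH chi-squared` = stat),
                 parameter = c(df = 1), p.value = pval,
                 method = "Mantel-Haenszel chi-square test for linear trend",
                 data.name = paste(deparse(substitute(events)), "by score"),
                 scores = scores),
            class = "htest")
}

#' Kruskal--Wallis rank test across groups
#'
#' Compares a continuous variable across k groups by the tie-corrected
#' Kruskal--Wallis H statistic referred to chi-square with k - 1 degrees of
#' freedom.  Wraps the standard \code{stats::kruskal.test} behind the
#' package's validation surface; a fully tied sample (zero rank variance)
#' returns H = 0 by convention.
#'
#' @param groups list of numeric vectors, one per group.
#' @return object of class \code{htest}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_sewss("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop_sewss("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1) {
    return(structure(list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                          parameter = c(df = length(groups) - 1),
                          p.value = 1,
                          method = "Kruskal-Wallis rank sum test",
                          data.name = "groups"),
                     class = "htest"))
  }
  stats::kruskal.test(x, g)
}
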