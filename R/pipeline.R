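#' Run the full validation pipeline
#'
#' Loads (or generates) a cohort, scores every record (ISS level and SEWSS
#' grade), and computes the validation battery: per-level composition,
#' baseline and vascular rate tables, odds-ratio ladders against the
#' non-ischaemic reference, Mantel--Haenszel trend tests, Kruskal--Wallis
#' comparisons of the continuous baselines, inter-rater agreement when two
#' rater columns are present, and the time-to-healing analysis
#' (Kaplan--Meier by level, log-rank, Cox against the severe reference).
#' All randomness flows from the single config seed, so a rerun with the
#' same config is byte-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{sewss_report} with the cohort and one element
#'   per report section.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort_csv(config$cohort_path, strict = config$strict)
  } else {
    generate_cohort(config$generator, seed = config$seed)
  }
  if (nrow(cohort) == 0) {
    return(structure(list(cohort = cohort, no_data = TRUE,
                          sections = "no data: empty cohort"),
                     class = "sewss_report"))
  }
  cohort <- score_cohort(cohort, config$scoring, na_unassessable = TRUE)
  lv <- factor(cohort$iss, levels = 0:3)
  comp <- table(lv)
  n_lv <- as.integer(comp)

  # per-level counts of the categorical rows, with outcome counts
  pulse_palpable <- function(g) !is.na(g) & g < 3
  cat_rows <- rbind(
    male = tapply(cohort$sex == "male", lv, sum, default = 0L),
    smoking = tapply(cohort$smoking, lv, sum, default = 0L),
    pulse_dorsalis_palpable = tapply(pulse_palpable(cohort$pulse_dorsalis), lv, sum, default = 0L),
    pulse_tibialis_palpable = tapply(pulse_palpable(cohort$pulse_tibialis), lv, sum, default = 0L),
    wound_healing = tapply(cohort$outcome == "healed", lv, sum, default = 0L),
    major_amputation = tapply(cohort$outcome == "major_amputation", lv, sum, default = 0L),
    abandonment = tapply(cohort$outcome == "abandoned", lv, sum, default = 0L),
    early_death = tapply(cohort$outcome == "early_death", lv, sum, default = 0L))
  cat_rows[is.na(cat_rows)] <- 0
  rates <- rate_table(cat_rows, col_totals = n_lv)

  # continuous baselines: per-level mean +/- sd plus Kruskal-Wallis
  cont_vars <- c("age", "diabetes_duration", "hba1c", "wound_history",
                 "wound_size", "sewss_sum", "abi", "tbi")
  cont_vars <- intersect(cont_vars, names(cohort))
  baseline <- do.call(rbind, lapply(cont_vars, function(v) {
    m <- tapply(cohort[[v]], lv, mean, na.rm = TRUE)
    s <- tapply(cohort[[v]], lv, stats::sd, na.rm = TRUE)
    groups <- split(cohort[[v]][!is.na(cohort[[v]])], lv[!is.na(cohort[[v]])])
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    p <- if (length(groups) >= 2) kruskal_wallis(groups)$p.value else NA_real_
    data.frame(variable = v, t(round_half_up(m, 2)), p_value = p,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))

  # outcome statistics vs ISS level
  outcome_rows <- c("wound_healing", "major_amputation", "abandonment",
                    "early_death")
  or_tab <- do.call(rbind, lapply(outcome_rows, function(o) {
    ev <- cat_rows[o, ]
    # wound healing: OR reported for failure, rates for success
    if (o == "wound_healing") ev <- n_lv - ev
    if (n_lv[1] > 0) {
      or_ladder(ev, n_lv, outcome_name = o, conf_level = config$conf_level)
    } else NULL
  }))
  trends <- lapply(outcome_rows, function(o)
    mh_trend_test(cat_rows[o, ], n_lv, scores = config$trend_scores))
  names(trends) <- outcome_rows

  agreement <- NULL
  if (all(c("rater_a", "rater_b") %in% names(cohort))) {
    overall <- cohen_kappa(table(factor(cohort$rater_a, levels = 0:3),
                                 factor(cohort$rater_b, levels = 0:3)))
    agreement <- list(overall = overall,
                      per_level = per_level_dichotomous_kappa(
                        cohort$rater_a, cohort$rater_b))
  }

  ev <- as.integer(cohort$outcome == "healed")
  km <- km_by_group(cohort$time_to_event, ev, cohort$iss)
  lr <- if (length(unique(cohort$iss)) >= 2 && sum(ev) > 0)
    logrank_test(cohort$time_to_event, ev, cohort$iss) else NULL
  cox <- if (length(unique(cohort$iss)) >= 2 && sum(ev) > 0)
    tryCatch(cox_by_level(cohort$time_to_event, ev, cohort$iss),
             error = function(e) NULL) else NULL

  structure(list(cohort = cohort, composition = comp, counts = cat_rows,
                 rates = rates, baseline = baseline, or_ladder = or_tab,
                 trend_tests = trends, agreement = agreement,
                 km = km, logrank = lr, cox = cox, no_data = FALSE),
            class = "sewss_report")
}

#' @export
print.sewss_report <- function(x, ...) {
  if (isTRUE(x$no_data)) { cat("sewss report: no data\n"); return(invisible(x)) }
  cat("sewss validation report\n")
  cat("ISS composition:", paste(x$composition, collapse = "/"),
      "(levels 0-3)\n\n")
  cat("Rates (% per level):\n"); print(x$rates); cat("\n")
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank chi-squared = %.2f, df = %d, p = %.3g\n",
                x$logrank$statistic, x$logrank$parameter, x$logrank$p.value))
  }
  invisible(x)
}

fmt_num <- function(x, d = 2) formatC(x, digits = d, format = "f")

#' Write a report bundle
#'
#' Renders a \code{\link{run_pipeline}} result to files: rate tables as CSV,
#' a markdown summary with cells formatted "count (percent)" and odds ratios
#' as "[OR, 95% C.I.]" mirroring the published table conventions, and a JSON
#' dump of every computed statistic.
#'
#' @param report a \code{sewss_report}.
#' @param dir output directory (created if needed).
#' @param formats subset of \code{c("csv", "markdown", "json")}.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("csv", "markdown", "json")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (isTRUE(report$no_data)) {
    f <- file.path(dir, "report.md")
    writeLines(c("# Validation report", "", "no data: empty cohort"), f)
    return(invisible(f))
  }
  if ("csv" %in% formats) {
    f <- file.path(dir, "rates.csv")
    utils::write.csv(data.frame(row = rownames(report$rates), report$rates,
                                check.names = FALSE), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "odds_ratios.csv")
    utils::write.csv(report$or_ladder, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "baseline.csv")
    utils::write.csv(report$baseline, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("markdown" %in% formats) {
    md <- c("# Validation report", "",
            paste0("ISS composition (levels 0-3): ",
                   paste(report$composition, collapse = "/")), "",
            "## Outcome and test rates by ISS level", "",
            paste0("| row | ", paste(colnames(report$rates), collapse = " | "),
                   " |"),
            paste0("|---", strrep("|---", ncol(report$rates)), "|"))
    for (r in rownames(report$rates)) {
      cells <- sprintf("%d (%s)", report$counts[r, ],
                       fmt_num(report$rates[r, ], 1))
      md <- c(md, paste0("| ", r, " | ", paste(cells, collapse = " | "), " |"))
    }
    md <- c(md, "", "## Odds ratios vs non-ischaemic reference (level 0)", "")
    if (!is.null(report$or_ladder))
      for (i in seq_len(nrow(report$or_ladder))) {
        o <- report$or_ladder[i, ]
        md <- c(md, sprintf("- %s, level %d: [%s, %s-%s]", o$outcome, o$level,
                            fmt_num(o$or, 1), fmt_num(o$ci_low, 1),
                            fmt_num(o$ci_high, 1)))
      }
    md <- c(md, "", "## Trend tests (Mantel-Haenszel chi-square, df 1)", "")
    for (nm in names(report$trend_tests)) {
      t <- report$trend_tests[[nm]]
      md <- c(md, sprintf("- %s: chi2 = %s, p = %.3g", nm,
                          fmt_num(t$statistic, 2), t$p.value))
    }
    if (!is.null(report$agreement)) {
      md <- c(md, "", "## Inter-rater agreement", "",
              sprintf("- overall kappa = %s", fmt_num(report$agreement$overall$kappa, 3)),
              sprintf("- per level: %s",
                      paste(names(report$agreement$per_level),
                            fmt_num(report$agreement$per_level, 3),
                            sep = " = ", collapse = ", ")))
    }
    if (!is.null(report$logrank))
      md <- c(md, "", "## Time to healing", "",
              sprintf("- log-rank chi2 = %s (df %d), p = %.3g",
                      fmt_num(report$logrank$statistic, 2),
                      report$logrank$parameter, report$logrank$p.value))
    if (!is.null(report$cox))
      md <- c(md, sprintf("- Cox HR %s = %s [%s-%s]",
                          names(report$cox$coef), fmt_num(report$cox$hr, 2),
                          fmt_num(report$cox$ci_low, 2),
                          fmt_num(report$cox$ci_high, 2)))
    f <- file.path(dir, "report.md")
    writeLines(md, f)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    j <- list(composition = as.integer(report$composition),
              counts = as.data.frame(report$counts),
              rates = as.data.frame(report$rates),
              or_ladder = report$or_ladder,
              trend = lapply(report$trend_tests, function(t)
                list(statistic = unname(t$statistic), p = t$p.value)),
              agreement = if (!is.null(report$agreement))
                list(overall = report$agreement$overall$kappa,
                     per_level = as.list(report$agreement$per_level)),
              logrank = if (!is.null(report$logrank))
                list(statistic = unname(report$logrank$statistic),
                     df = unname(report$logrank$parameter),
                     p = report$logrank$p.value),
              cox = if (!is.null(report$cox))
                list(term = names(report$cox$coef), hr = unname(report$cox$hr),
                     ci_low = unname(report$cox$ci_low),
                     ci_high = unname(report$cox$ci_high)))
    f <- file.path(dir, "report.json")
    jsonlite::write_json(j, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}
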