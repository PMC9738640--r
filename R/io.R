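#' Cohort CSV schema
#'
#' Column names of the flat per-patient cohort table: demographics, raw
#' vascular measurements, the ten SEWSS factor subscores, the study outcome
#' and the time to event.  Missing values are encoded as empty fields.
#'
#' @return list with \code{required} and \code{optional} column names.
#' @export
cohort_schema <- function() {
  list(required = c("id", "age", "sex", "diabetes_duration", "hba1c",
                    "smoking", "wound_history", "wound_size",
                    "arm_systolic_left", "arm_systolic_right",
                    "ankle_systolic_dp", "ankle_systolic_tp", "toe_systolic",
                    "pulse_dorsalis", "pulse_tibialis", "waveform",
                    sewss_factor_names(), "outcome", "time_to_event"),
       optional = c("true_level", "delayed_death", "abi", "tbi", "iss",
                    "iss_label", "iss_decided_by", "sewss_sum", "sewss_grade",
                    "rater_a", "rater_b"))
}

outcome_levels <- function() c("healed", "major_amputation", "abandoned",
                               "early_death", "censored")

# per-row validation; returns character vector of messages (empty if clean)
validate_cohort_rows <- function(df) {
  msgs <- character(0)
  bad <- function(cond, what) {
    rows <- which(cond & !is.na(cond))
    if (length(rows))
      msgs <<- c(msgs, paste0("row ", rows, ": ", what))
  }
  bad(df$arm_systolic_left <= 0 | df$arm_systolic_right <= 0,
      "non-positive arm pressure")
  for (v in c("ankle_systolic_dp", "ankle_systolic_tp", "toe_systolic"))
    bad(df[[v]] < 0, paste("negative", v))
  for (v in c("pulse_dorsalis", "pulse_tibialis"))
    bad(!(df[[v]] %in% 0:3), paste(v, "outside 0..3"))
  bad(!is.na(df$waveform) &
        !(df$waveform %in% names(scoring_config()$waveform_map)),
      "unknown waveform category")
  for (v in sewss_factor_names())
    bad(is.na(df[[v]]) | !(df[[v]] %in% 0:3), paste(v, "outside 0..3"))
  bad(!(df$outcome %in% outcome_levels()), "unknown outcome")
  bad(is.na(df$time_to_event) | df$time_to_event <= 0,
      "non-positive time_to_event")
  msgs
}

#' Read a cohort CSV
#'
#' Reads and validates a flat per-patient cohort table.  A header missing
#' required columns is a hard error.  Invalid rows are skipped with a
#' warning naming the rows, or raise an error in strict mode.
#'
#' @param path CSV file path.
#' @param strict raise an error on any invalid row instead of skipping.
#' @return validated cohort data.frame.
#' @export
read_cohort_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_sewss("cohort file not found: ", path)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  need <- cohort_schema()$required
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_sewss("malformed header, missing column(s): ",
               paste(missing_cols, collapse = ", "))
  if ("smoking" %in% names(df)) df$smoking <- as.logical(df$smoking)
  if ("delayed_death" %in% names(df))
    df$delayed_death <- as.logical(df$delayed_death)
  msgs <- validate_cohort_rows(df)
  if (length(msgs)) {
    if (strict) stop_sewss("invalid cohort rows:\n  ",
                           paste(msgs, collapse = "\n  "))
    rows <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", msgs)))
    warning(length(rows), " invalid row(s) skipped: ",
            paste(utils::head(msgs, 5), collapse = "; "), call. = FALSE)
    df <- df[-rows, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a cohort CSV
#'
#' Writes the flat cohort table with full double precision so that a
#' write-read round trip reproduces every typed field exactly.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (v in names(out)) {
    if (is.double(out[[v]]))
      out[[v]] <- ifelse(is.na(out[[v]]), NA, sprintf("%.17g", out[[v]]))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param cohort_path path to a cohort CSV, or \code{NULL} to generate a
#'   synthetic cohort from \code{generator}.
#' @param generator a \code{\link{cohort_params}} object.
#' @param scoring a \code{\link{scoring_config}}.
#' @param conf_level confidence level for odds-ratio and hazard-ratio CIs.
#' @param trend_scores scores for the ordinal ISS levels in the trend test.
#' @param seed master seed for every stochastic stage.
#' @param strict strict row validation when reading a cohort file.
#' @return list of class \code{sewss_pipeline_config}.
#' @export
pipeline_config <- function(cohort_path = NULL,
                            generator = cohort_params(),
                            scoring = scoring_config(),
                            conf_level = 0.95,
                            trend_scores = 0:3,
                            seed = 1L,
                            strict = FALSE) {
  stopifnot(conf_level > 0, conf_level < 1)
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop_sewss("cohort file not found: ", cohort_path)
  structure(list(cohort_path = cohort_path, generator = generator,
                 scoring = scoring, conf_level = conf_level,
                 trend_scores = trend_scores, seed = as.integer(seed),
                 strict = strict),
            class = "sewss_pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Reads the band tables, precedence order, generator parameters and
#' statistics options from a JSON file; absent keys keep their defaults.
#' Recognised scoring keys: \code{abi_bands}, \code{tbi_bands},
#' \code{waveform_map}, \code{test_precedence}, \code{incompressible_above};
#' generator keys mirror the \code{\link{cohort_params}} arguments.
#'
#' @param path JSON file path.
#' @return \code{sewss_pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(scoring_config, c(
    j$scoring[intersect(names(j$scoring),
                        names(formals(scoring_config)))]))
  if (!is.null(j$scoring$waveform_map))
    sc$waveform_map <- unlist(j$scoring$waveform_map)
  gen_args <- j$generator[intersect(names(j$generator %||% list()),
                                    names(formals(cohort_params)))]
  gen <- do.call(cohort_params, gen_args %||% list())
  pipeline_config(cohort_path = j$cohort_path,
                  generator = gen, scoring = sc,
                  conf_level = j$conf_level %||% 0.95,
                  trend_scores = j$trend_scores %||% 0:3,
                  seed = j$seed %||% 1L,
                  strict = isTRUE(j$strict))
}
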