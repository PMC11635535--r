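COHORT_COLUMNS <- c("participant_id", "domain", "arm", "enroll_week",
                    "week", "egfr", "uacr", "on_treatment")

#' Write a cohort to long-format CSV
#'
#' Columns, in order: `participant_id, domain, arm, enroll_week, week,
#' egfr, uacr, on_treatment`.  UTF-8, comma separator, `.` decimal point,
#' header row.  Numeric values keep full double precision so a write/read
#' round trip is exact to well below 1e-9.
#'
#' @param path output file path.
#' @param data analysis `data.frame` from [cohort_data()] (or a
#'   previously read cohort).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(path, data) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols))
    stop_invalid(sprintf("cohort data lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  write.csv(data[, COHORT_COLUMNS], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format cohort CSV
#'
#' The header must match the declared schema exactly (names and order).
#' Every row is validated against the visit-record invariants (positive
#' eGFR and UACR, non-negative weeks); violations are reported with the
#' file line number.
#'
#' @param path input file path.
#' @return A validated analysis `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), COHORT_COLUMNS))
    stop_invalid(sprintf(
      "cohort CSV header must be exactly: %s (got: %s)",
      paste(COHORT_COLUMNS, collapse = ","), paste(names(df), collapse = ",")))
  df$on_treatment <- as.logical(df$on_treatment)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  check <- function(bad, what) {
    if (any(bad))
      stop_invalid(sprintf("invalid %s at line %d of %s", what,
                           line[which(bad)[1]], path))
  }
  for (col in c("enroll_week", "week", "egfr", "uacr"))
    check(!is.finite(df[[col]]), sprintf("non-numeric `%s`", col))
  check(df$egfr <= 0, "`egfr` (must be positive)")
  check(df$uacr <= 0, "`uacr` (must be positive)")
  check(df$week < 0, "`week` (must be non-negative)")
  check(df$enroll_week < 0, "`enroll_week` (must be non-negative)")
  check(is.na(df$on_treatment), "`on_treatment` (must be logical)")
  df
}

#' Prepare user-supplied visit data for analysis
#'
#' Accepts either the cohort schema directly or a table carrying serum
#' creatinine (`scr_mg_dl`) with `age` and `sex` columns instead of
#' `egfr`; creatinine is converted through [egfr_ckd_epi_2021()].
#'
#' @param df a `data.frame`.
#' @return A `data.frame` with an `egfr` column.
#' @export
prepare_analysis_data <- function(df) {
  if (!"egfr" %in% names(df)) {
    needed <- c("scr_mg_dl", "age", "sex")
    if (!all(needed %in% names(df)))
      stop_invalid("data must contain `egfr` or `scr_mg_dl` + `age` + `sex`")
    df$egfr <- egfr_ckd_epi_2021(df$scr_mg_dl, df$age, df$sex)
  }
  df
}

# Strip closures/classes so a trial result serializes cleanly to JSON.
result_to_list <- function(x) {
  rec_to_list <- function(r) {
    list(
      interim_index = r$interim_index,
      calendar_week = r$calendar_week,
      decision = r$decision,
      reason = r$reason,
      probabilities = as.list(r$probabilities),
      flags = {
        f <- unclass(r$flags)
        f[c("uacr_futility_eligible", "egfr_futility_eligible",
            "success_eligible", "full_window_eligible")]
      },
      uacr_summary = if (!is.null(r$uacr_summary)) unclass(r$uacr_summary),
      slope_summary = if (!is.null(r$slope_summary)) unclass(r$slope_summary)
    )
  }
  list(
    final_decision = x$final_decision,
    decision_week = x$decision_week,
    n_randomized = x$n_randomized,
    n_intervention = x$n_intervention,
    seed = x$seed,
    interims = lapply(x$interims, rec_to_list)
  )
}

write_result_json <- function(x, path) {
  jsonlite::write_json(result_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

# Run manifest: provenance record written next to every CLI output.
write_manifest <- function(path, command, seed, config_path, output_paths) {
  jsonlite::write_json(list(
    command = command,
    seed = seed,
    config_path = config_path,
    version = as.character(utils::packageVersion("adaptckd")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_paths = as.list(output_paths)
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
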