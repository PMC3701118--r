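trial_log_col_spec <- function() {
  readr::cols(
    subject_id = readr::col_integer(),
    condition = readr::col_character(),
    experiment = readr::col_character(),
    phase = readr::col_integer(),
    finger = readr::col_character(),
    trial = readr::col_integer(),
    excluded = readr::col_logical(),
    track_side = readr::col_character(),
    diff_hz = readr::col_double(),
    step_offset = readr::col_integer(),
    f1_hz = readr::col_double(),
    f2_hz = readr::col_double(),
    dur1_s = readr::col_double(),
    dur2_s = readr::col_double(),
    comparison_first = readr::col_logical(),
    response = readr::col_character(),
    correct_answer = readr::col_character(),
    correct = readr::col_logical(),
    feedback = readr::col_character(),
    points = readr::col_double(),
    cumulative_points = readr::col_double(),
    sigma_readout_hz = readr::col_double(),
    criterion_hz = readr::col_double(),
    reversal = readr::col_logical()
  )
}

#' Write a trial log to CSV
#'
#' The log's fixed column set (see [read_trial_log()]) is written with full
#' numeric precision, so `write_trial_log()` followed by [read_trial_log()]
#' is lossless.
#'
#' @param trials A trial-log tibble (e.g. `run_experiment(...)$trials`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  missing_cols <- setdiff(trial_log_columns(), names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial log is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  readr::write_csv(trials[, trial_log_columns()], path, na = "NA")
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Reads a CSV produced by [write_trial_log()] with a fixed column
#' specification; malformed rows raise an error naming the offending line.
#'
#' @param path Path to a trial-log CSV.
#' @return A trial-log tibble.
#' @export
read_trial_log <- function(path) {
  out <- suppressWarnings(
    readr::read_csv(
      path,
      col_types = trial_log_col_spec(), progress = FALSE,
      show_col_types = FALSE
    )
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    stop(
      "malformed trial log at line ", probs$row[1] + 1L, ": ",
      probs$expected[1], " expected, got ", probs$actual[1],
      call. = FALSE
    )
  }
  missing_cols <- setdiff(trial_log_columns(), names(out))
  if (length(missing_cols) > 0L) {
    stop("trial log is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Export session or cohort results as JSON
#'
#' For a `tact_experiment`, writes the tidy one-row summary together with
#' the reward schedule and the full feedback probability table; for a
#' cohort tibble, writes the per-subject rows and the [cohort_statistics()]
#' table.
#'
#' @param x A `tact_experiment` or a cohort tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  payload <- if (inherits(x, "tact_experiment")) {
    list(
      summary = tidy(x),
      reward_schedule = unclass(x$schedule),
      feedback_p_same = as.data.frame(x$feedback)
    )
  } else if (is.data.frame(x)) {
    list(
      subjects = as.data.frame(x),
      statistics = tidy(cohort_statistics(x))
    )
  } else {
    stop("`x` must be a tact_experiment or a cohort tibble.", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
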