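trial_columns <- c("participant_id", "task", "day", "session", "trial",
                   "distance_m", "stimulus", "response")

#' Write a trial table to CSV
#'
#' One trial per row, long format, comma-separated with a header. Column
#' order is fixed and distances are serialized at 2 decimals, so
#' `write_trials()` then [read_trials()] then `write_trials()` is
#' byte-identical. Unset responses are written as empty fields.
#'
#' @param trials Trial tibble (see [schedule_trials()]).
#' @param path Output file path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- trials[trial_columns]
  out$distance_m <- sprintf("%.2f", out$distance_m)
  readr::write_csv(out, path, na = "")
  invisible(trials)
}

#' Read and validate a trial table
#'
#' Reads a CSV written by [write_trials()] (or hand-assembled in the same
#' format) and validates every row, reporting offending rows by their file
#' line number (the header is line 1):
#' * `task` must be `detection` or `localization`;
#' * `stimulus` must be `left_reflector`, `right_reflector` or
#'   `no_reflector`, and localization rows never carry `no_reflector`;
#' * `response` must be `yes`/`no` on detection rows and `left`/`right` on
#'   localization rows (empty = unset);
#' * `distance_m` must be a positive number;
#' * `(participant_id, task, day, session, trial)` keys must be unique.
#'
#' @param path CSV file path.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  if (!identical(header, trial_columns)) {
    stop("unexpected header; expected exactly: ",
         paste(trial_columns, collapse = ","), call. = FALSE)
  }
  d <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      participant_id = readr::col_character(),
      task = readr::col_character(),
      day = readr::col_integer(),
      session = readr::col_integer(),
      trial = readr::col_integer(),
      distance_m = readr::col_double(),
      stimulus = readr::col_character(),
      response = readr::col_character()))

  line <- seq_len(nrow(d)) + 1L # file line numbers; header is line 1
  fail <- function(bad, what) {
    if (any(bad)) {
      stop(what, " at line(s) ", paste(utils::head(line[bad], 10),
                                       collapse = ", "),
           if (sum(bad) > 10) " ..." else "", call. = FALSE)
    }
  }

  fail(is.na(d$task) | !d$task %in% task_labels, "unknown task")
  fail(is.na(d$stimulus) | !d$stimulus %in% stimulus_labels,
       "unknown stimulus")
  fail(d$task == "localization" & d$stimulus == "no_reflector",
       "no_reflector is not a localization stimulus")
  fail(is.na(d$distance_m) | d$distance_m <= 0,
       "distance_m must be a positive number")
  fail(is.na(d$day) | d$day < 1 | is.na(d$session) | d$session < 1 |
         is.na(d$trial) | d$trial < 1, "invalid day/session/trial index")
  has_resp <- !is.na(d$response)
  fail(has_resp & d$task == "detection" & !d$response %in% c("yes", "no"),
       "detection responses must be yes/no")
  fail(has_resp & d$task == "localization" &
         !d$response %in% c("left", "right"),
       "localization responses must be left/right")
  key <- paste(d$participant_id, d$task, d$day, d$session, d$trial,
               sep = "\x1f")
  fail(duplicated(key), "duplicate (participant, task, day, session, trial)")

  d
}

#' Write a JSON report for fits, summaries or ANOVA tables
#'
#' Serializes tibbles/lists produced by the pipeline (fit summaries,
#' contrast tables, ANOVA tables) together with provenance metadata
#' (package version, seed, config) to pretty-printed JSON.
#'
#' @param x A list or data frame to serialize.
#' @param path Output path.
#' @param meta Optional named list of run metadata merged into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, meta = list()) {
  payload <- list(
    generated_by = paste0("echosdt ",
                          as.character(utils::packageVersion("echosdt"))),
    meta = meta,
    results = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
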