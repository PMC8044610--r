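#' Automated-rail echolocation experiment design
#'
#' Describes the schedule of a two-task echolocation experiment run with an
#' automated rail-and-disk apparatus: a method-of-constant-stimuli design in
#' which a fixed set of reflector distances is presented in random order,
#' many times per session, over several days. The defaults reproduce the
#' reference design: 10 distances from 1.00 to 4.25 m, 4 days of 10 sessions
#' of 50 trials per task (each distance 5 times per session), detection-task
#' reflector probabilities 0.25/0.25/0.5 for left/right/absent, localization
#' probabilities 0.5/0.5 for left/right, and day 1 treated as practice and
#' excluded from analysis.
#'
#' @param distances_m Strictly increasing positive reflector distances (m).
#' @param days Number of testing days per task.
#' @param sessions_per_day Sessions per day.
#' @param reps_per_distance_per_session How often each distance occurs per
#'   session (so a session has `length(distances_m) * reps` trials).
#' @param detection_stim_probs Named or ordered probabilities for the
#'   detection-task reflector positions `(left_reflector, right_reflector,
#'   no_reflector)`; must sum to 1.
#' @param localization_stim_probs Probabilities for `(left_reflector,
#'   right_reflector)` in the localization task; must sum to 1.
#' @param practice_days Integer vector of day indices dropped by
#'   [analysis_subset()].
#' @return An object of class `echo_design`.
#' @examples
#' design <- echo_design()
#' design
#' trials_per_session(design)
#' @export
echo_design <- function(distances_m = c(1.00, 1.36, 1.72, 2.08, 2.44,
                                        2.81, 3.17, 3.53, 3.89, 4.25),
                        days = 4L,
                        sessions_per_day = 10L,
                        reps_per_distance_per_session = 5L,
                        detection_stim_probs = c(left_reflector = 0.25,
                                                 right_reflector = 0.25,
                                                 no_reflector = 0.5),
                        localization_stim_probs = c(left_reflector = 0.5,
                                                    right_reflector = 0.5),
                        practice_days = 1L) {
  stopifnot(length(distances_m) >= 1, all(is.finite(distances_m)))
  if (any(distances_m <= 0) || is.unsorted(distances_m, strictly = TRUE)) {
    stop("`distances_m` must be strictly increasing and positive", call. = FALSE)
  }
  for (n in c("days", "sessions_per_day", "reps_per_distance_per_session")) {
    v <- get(n)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != as.integer(v)) {
      stop("`", n, "` must be a positive integer", call. = FALSE)
    }
  }
  check_probs <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("`", what, "` must be ", k, " non-negative probabilities summing to 1",
           call. = FALSE)
    }
  }
  check_probs(detection_stim_probs, 3, "detection_stim_probs")
  check_probs(localization_stim_probs, 2, "localization_stim_probs")
  practice_days <- as.integer(practice_days)
  if (anyNA(practice_days) || any(practice_days < 1 | practice_days > days)) {
    stop("`practice_days` must be day indices within 1..days", call. = FALSE)
  }

  structure(
    list(
      distances_m = as.numeric(distances_m),
      days = as.integer(days),
      sessions_per_day = as.integer(sessions_per_day),
      reps_per_distance_per_session = as.integer(reps_per_distance_per_session),
      detection_stim_probs = stats::setNames(
        as.numeric(detection_stim_probs),
        c("left_reflector", "right_reflector", "no_reflector")),
      localization_stim_probs = stats::setNames(
        as.numeric(localization_stim_probs),
        c("left_reflector", "right_reflector")),
      practice_days = practice_days
    ),
    class = "echo_design"
  )
}

#' @export
print.echo_design <- function(x, ...) {
  cat("<echo_design>\n")
  cat("  distances (m): ", paste(sprintf("%.2f", x$distances_m), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  %d day(s) x %d session(s) x %d trials/session per task\n",
              x$days, x$sessions_per_day, trials_per_session(x)))
  cat("  detection stimulus probs: ",
      paste(sprintf("%s=%.2f", names(x$detection_stim_probs),
                    x$detection_stim_probs), collapse = ", "), "\n", sep = "")
  cat("  localization stimulus probs: ",
      paste(sprintf("%s=%.2f", names(x$localization_stim_probs),
                    x$localization_stim_probs), collapse = ", "), "\n", sep = "")
  cat("  practice day(s): ", paste(x$practice_days, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname echo_design
#' @param design An `echo_design`.
#' @export
trials_per_session <- function(design) {
  stopifnot(inherits(design, "echo_design"))
  length(design$distances_m) * design$reps_per_distance_per_session
}

task_labels <- c("detection", "localization")
stimulus_labels <- c("left_reflector", "right_reflector", "no_reflector")

# Deterministic sub-seed expansion: a polynomial string hash folded into the
# root seed, kept below 2^31 so set.seed() gets a valid integer. Doubles hold
# the intermediate products exactly (all < 2^53).
derive_seed <- function(root_seed, ...) {
  key <- paste(c(...), collapse = "\x1f")
  m <- 2147483629
  h <- root_seed %% m
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

#' Schedule the trials of one task for one participant
#'
#' Builds the trial table implied by an [echo_design()]: per session an
#' independently shuffled sequence containing each distance exactly
#' `reps_per_distance_per_session` times, with the reflector position drawn
#' i.i.d. per trial from the task's stimulus probabilities (the localization
#' task never uses the no-reflector position). Responses are left `NA`;
#' fill them with [simulate_responses()] or real data.
#'
#' The root seed is expanded deterministically per (participant, task, day,
#' session), so any subset of the schedule is reproducible in isolation and
#' the same seed yields a bit-identical table.
#'
#' @param design An [echo_design()].
#' @param task `"detection"` or `"localization"`.
#' @param participant Participant label (default `"P1"`).
#' @param seed Integer root seed.
#' @return A tibble with one row per trial: `participant_id`, `task`, `day`,
#'   `session`, `trial`, `distance_m`, `stimulus`, `response` (`NA`).
#' @examples
#' sched <- schedule_trials(echo_design(), "detection", seed = 1)
#' nrow(sched)
#' @export
schedule_trials <- function(design, task, participant = "P1", seed = 1L) {
  stopifnot(inherits(design, "echo_design"))
  task <- match.arg(task, task_labels)
  probs <- if (task == "detection") design$detection_stim_probs else
    design$localization_stim_probs
  base_distances <- rep(design$distances_m,
                        each = design$reps_per_distance_per_session)
  n_sess_trials <- length(base_distances)

  grid <- tidyr::expand_grid(day = seq_len(design$days),
                             session = seq_len(design$sessions_per_day))
  sessions <- purrr::pmap(grid, function(day, session) {
    s <- derive_seed(seed, "schedule", participant, task, day, session)
    withr::with_seed(s, {
      dist <- sample(base_distances)
      stim <- sample(names(probs), n_sess_trials, replace = TRUE, prob = probs)
    })
    tibble::tibble(
      participant_id = participant, task = task,
      day = day, session = session, trial = seq_len(n_sess_trials),
      distance_m = dist, stimulus = stim,
      response = NA_character_
    )
  })
  dplyr::bind_rows(sessions)
}

#' Encode signal-present and yes-response indicators
#'
#' Fixes the SDT coding used throughout fitting. Detection: the signal is
#' present (`signal = 1`) whenever either reflector faces the listener, and
#' `yes = 1` for a "yes, reflecting" response. Localization: the left side
#' is arbitrarily defined as signal, so `signal = 1` for a left reflector
#' and `yes = 1` for a "left" response.
#'
#' @param trials A trial tibble (see [schedule_trials()]).
#' @return `trials` with integer columns `signal` and `yes` appended (`yes`
#'   is `NA` where the response is missing).
#' @export
encode_sdt <- function(trials) {
  trials <- tibble::as_tibble(trials)
  bad_task <- setdiff(unique(trials$task), task_labels)
  if (length(bad_task)) {
    stop("unknown task label(s): ", paste(bad_task, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(
    trials,
    signal = dplyr::if_else(
      .data$task == "detection",
      as.integer(.data$stimulus != "no_reflector"),
      as.integer(.data$stimulus == "left_reflector")),
    yes = dplyr::case_when(
      is.na(.data$response) ~ NA_integer_,
      .data$task == "detection" ~ as.integer(.data$response == "yes"),
      TRUE ~ as.integer(.data$response == "left"))
  )
}

#' Simulate observer responses for a trial schedule
#'
#' Draws each response as an independent Bernoulli trial with probability
#' given by the SDT observation model [p_yes()], using the observer's d' and
#' c for the trial's task and distance. Responses are stored as task-native
#' labels (`yes`/`no` for detection, `left`/`right` for localization).
#' Deterministic given `seed`: the root seed is expanded per (participant,
#' task, day, session) exactly as in [schedule_trials()].
#'
#' @param trials Trial tibble with unset responses.
#' @param observer An [observer_categorical()] or [observer_exponential()].
#' @param seed Integer root seed for the response draws.
#' @return `trials` with the `response` column filled.
#' @examples
#' obs <- observer_exponential(3, -0.5, 2, -0.6, 0, 0)
#' trials <- schedule_trials(echo_design(), "detection", seed = 1) |>
#'   simulate_responses(obs, seed = 2)
#' table(trials$response)
#' @export
simulate_responses <- function(trials, observer, seed = 1L) {
  trials <- encode_sdt(trials)
  dp <- observer_dprime(observer, trials$task, trials$distance_m)
  cc <- observer_criterion(observer, trials$task, trials$distance_m)
  trials$.p_yes <- p_yes(dp, cc, trials$signal)

  trials |>
    dplyr::group_by(.data$participant_id, .data$task, .data$day,
                    .data$session) |>
    dplyr::group_modify(function(df, key) {
      s <- derive_seed(seed, "responses", key$participant_id, key$task,
                       key$day, key$session)
      draw <- withr::with_seed(s, stats::runif(nrow(df)) < df$.p_yes)
      df$response <- if (key$task == "detection") {
        dplyr::if_else(draw, "yes", "no")
      } else {
        dplyr::if_else(draw, "left", "right")
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".p_yes") |>
    dplyr::arrange(.data$participant_id, .data$task, .data$day,
                   .data$session, .data$trial) |>
    dplyr::mutate(yes = dplyr::if_else(
      .data$task == "detection",
      as.integer(.data$response == "yes"),
      as.integer(.data$response == "left")))
}

#' Drop practice-day trials
#'
#' Returns the analysis subset of a trial table: all trials whose `day` is
#' listed in the design's `practice_days` are removed. Under the default
#' design this leaves 3 days x 10 sessions x 50 trials = 1,500 trials per
#' task and participant, i.e. 150 per distance, task and participant.
#'
#' @param trials Trial tibble.
#' @param design The [echo_design()] the trials came from.
#' @return The filtered tibble.
#' @export
analysis_subset <- function(trials, design) {
  stopifnot(inherits(design, "echo_design"))
  dplyr::filter(tibble::as_tibble(trials),
                !(.data$day %in% design$practice_days))
}

#' Simulate a full two-task experiment for several participants
#'
#' Convenience wrapper: schedules and simulates both tasks for each
#' participant under a common root seed.
#'
#' @param design An [echo_design()].
#' @param observer Observer used for every participant, or a named list of
#'   observers keyed by participant label.
#' @param participants Character vector of participant labels.
#' @param seed Integer root seed.
#' @return A trial tibble covering all participants and both tasks.
#' @export
simulate_experiment <- function(design, observer,
                                participants = paste0("P", 1:10),
                                seed = 1L) {
  purrr::map(participants, function(pid) {
    obs <- if (is.list(observer) && !inherits(observer, "echo_observer")) {
      observer[[pid]]
    } else {
      observer
    }
    purrr::map(task_labels, function(tk) {
      schedule_trials(design, tk, participant = pid, seed = seed) |>
        simulate_responses(obs, seed = seed)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
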