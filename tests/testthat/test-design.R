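test_that("the default design reproduces the reference schedule", {
  d <- echo_design()
  expect_length(d$distances_m, 10)
  expect_equal(d$distances_m[1], 1.00)
  expect_equal(d$distances_m[10], 4.25)
  expect_equal(trials_per_session(d), 50)
  expect_equal(d$detection_stim_probs[["no_reflector"]], 0.5)
  expect_equal(d$practice_days, 1L)
})

test_that("design validation rejects malformed inputs", {
  expect_error(echo_design(distances_m = c(2, 1)), "increasing")
  expect_error(echo_design(days = 0), "positive integer")
  expect_error(echo_design(detection_stim_probs = c(0.3, 0.3, 0.3)),
               "summing to 1")
  expect_error(echo_design(practice_days = 9), "within")
  # a minimal 1-trial-per-session design is legal
  tiny <- echo_design(distances_m = 2.0, days = 1, sessions_per_day = 1,
                      reps_per_distance_per_session = 1, practice_days = 1)
  expect_equal(trials_per_session(tiny), 1)
})

test_that("schedules have the exact session distance multiset and counts", {
  d <- echo_design()
  tr <- schedule_trials(d, "detection", seed = 3)
  expect_equal(nrow(tr), 4 * 10 * 50)
  per_session <- tr |>
    dplyr::group_by(day, session) |>
    dplyr::summarise(ok = identical(sort(distance_m),
                                    sort(rep(d$distances_m, 5))),
                     .groups = "drop")
  expect_true(all(per_session$ok))
  # no-reflector frequency: binomial tolerance at n = 2000
  frac <- mean(tr$stimulus == "no_reflector")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("localization schedules never use the no-reflector position", {
  tr <- schedule_trials(echo_design(), "localization", seed = 3)
  expect_equal(sum(tr$stimulus == "no_reflector"), 0)
  expect_setequal(unique(tr$stimulus), c("left_reflector", "right_reflector"))
  expect_error(schedule_trials(echo_design(), "pointing"), "'arg'")
})

test_that("schedules are reproducible by seed and distinct across keys", {
  d <- echo_design(days = 1)
  a <- schedule_trials(d, "detection", seed = 9)
  b <- schedule_trials(d, "detection", seed = 9)
  expect_identical(a, b)
  c1 <- schedule_trials(d, "detection", seed = 10)
  expect_false(identical(a$distance_m, c1$distance_m))
  p2 <- schedule_trials(d, "detection", participant = "P2", seed = 9)
  expect_false(identical(a$distance_m, p2$distance_m))
})

test_that("signal and response coding follows the task conventions", {
  tr <- tibble::tibble(
    participant_id = "P1", task = c("detection", "detection", "detection",
                                    "localization", "localization"),
    day = 1L, session = 1L, trial = 1:5, distance_m = 1,
    stimulus = c("left_reflector", "right_reflector", "no_reflector",
                 "left_reflector", "right_reflector"),
    response = c("yes", "no", "yes", "left", "right"))
  enc <- encode_sdt(tr)
  expect_equal(enc$signal, c(1L, 1L, 0L, 1L, 0L))
  expect_equal(enc$yes, c(1L, 0L, 1L, 1L, 0L))
  expect_error(encode_sdt(dplyr::mutate(tr, task = "probing")),
               "unknown task")
})

test_that("analysis_subset drops exactly the practice days", {
  d <- echo_design()
  tr <- schedule_trials(d, "detection", seed = 1)
  kept <- analysis_subset(tr, d)
  expect_equal(nrow(kept), 1500) # 3 days x 10 sessions x 50 trials
  per_distance <- dplyr::count(kept, distance_m)
  expect_true(all(per_distance$n == 150))
  expect_identical(analysis_subset(tr, echo_design(practice_days = integer())),
                   tibble::as_tibble(tr))
  all_practice <- echo_design(practice_days = 1:4)
  expect_equal(nrow(analysis_subset(tr, all_practice)), 0)
})

test_that("simulated responses follow the observation model", {
  d <- echo_design(distances_m = 2, days = 1, sessions_per_day = 1,
                   reps_per_distance_per_session = 4000, practice_days = 1)
  # chance observer: yes-rate 0.5 regardless of stimulus
  tr <- schedule_trials(d, "detection", seed = 4)
  sim <- simulate_responses(tr, observer_categorical(
    distances_m = 2, d_prime_detection = 0, d_prime_localization = 0), seed = 5)
  expect_lt(abs(mean(sim$yes) - 0.5), 3 * sqrt(0.25 / nrow(sim)))
  # heavily conservative observer: yes-rate about Phi(-3)
  sim2 <- simulate_responses(tr, observer_categorical(
    distances_m = 2, c_detection = 3, c_localization = 3), seed = 6)
  p <- stats::pnorm(-3)
  expect_lt(abs(mean(sim2$yes) - p), 3 * sqrt(p * (1 - p) / nrow(sim2)) + 1e-4)
  # determinism
  expect_identical(simulate_responses(tr, fixture_observer(), seed = 7),
                   simulate_responses(tr, fixture_observer(), seed = 7))
})

test_that("closed-form estimates recover an exponential observer at large n", {
  # d'(1 m) = 3 exp(-0.5) ~ 1.82 with unbiased responding
  obs <- observer_exponential(3, -0.5, 3, -0.5, 0, 0)
  d <- echo_design(distances_m = 1, days = 1, sessions_per_day = 1,
                   reps_per_distance_per_session = 10000, practice_days = 1)
  sim <- schedule_trials(d, "detection", seed = 8) |>
    simulate_responses(obs, seed = 9)
  h <- mean(sim$yes[sim$signal == 1])
  f <- mean(sim$yes[sim$signal == 0])
  expect_equal(dprime_from_rates(h, f), 3 * exp(-0.5), tolerance = 0.1)
})

test_that("empirical rates converge to the p_yes probabilities", {
  # law-of-large-numbers check at n = 1e5 within 3 binomial SDs
  obs <- observer_exponential(2, -0.3, 1.5, -0.4, 0.2, -0.1)
  d <- echo_design(distances_m = 2, days = 1, sessions_per_day = 1,
                   reps_per_distance_per_session = 100000, practice_days = 1)
  sim <- schedule_trials(d, "localization", seed = 10) |>
    simulate_responses(obs, seed = 11)
  dp <- 1.5 * exp(-0.4 * 2)
  for (s in 0:1) {
    p_true <- p_yes(dp, -0.1, s)
    n_s <- sum(sim$signal == s)
    emp <- mean(sim$yes[sim$signal == s])
    expect_lt(abs(emp - p_true), 3 * sqrt(p_true * (1 - p_true) / n_s))
  }
})

test_that("categorical observers refuse off-grid distances", {
  obs <- observer_categorical(distances_m = c(1, 2), d_prime_detection = 1,
                              d_prime_localization = 1)
  expect_error(observer_dprime(obs, "detection", 3), "grid")
})
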