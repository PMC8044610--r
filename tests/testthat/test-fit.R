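test_that("the categorical fit has 40 ordered parameters on the full design", {
  fit <- fixture_fit("categorical")
  td <- tidy(fit)
  expect_equal(nrow(td), 40) # 2 tasks x 10 distances x (d', c)
  expect_equal(sum(td$parameter == "d_prime"), 20)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_true(all(is.finite(td$rhat)) && all(is.finite(td$ess)))
  g <- glance(fit)
  expect_equal(g$n_parameters, 40)
  expect_equal(g$n_trials, 3000)
})

test_that("the exponential fit has 6 parameters and recovers the truth", {
  fit <- fixture_fit("exponential")
  td <- tidy(fit)
  expect_equal(td$term, c("alpha0", "alpha1", "beta0", "beta1", "c0", "c1"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  # medians land near the generative parameters (posterior scale ~0.1-0.6)
  err <- abs(td$estimate - fixture_truth[td$term])
  expect_true(all(err < c(1, 0.3, 1.5, 0.5, 0.15, 0.15)))
  # and most intervals cover the truth outright
  covered <- td$conf.low <= fixture_truth[td$term] &
    fixture_truth[td$term] <= td$conf.high
  expect_gte(sum(covered), 5)
})

test_that("posterior medians agree with closed-form estimates at large n", {
  # two distances, thousands of trials per cell, interior rates
  obs <- observer_exponential(2.2, -0.35, 1.6, -0.45, 0.15, -0.1)
  per_cell <- 3000
  trials <- purrr::pmap_dfr(
    tidyr::expand_grid(task = c("detection", "localization"),
                       distance_m = c(1, 3)),
    function(task, distance_m) {
      stim_absent <- if (task == "detection") "no_reflector" else
        "right_reflector"
      tibble::tibble(
        participant_id = "P1", task = task, day = 1L, session = 1L,
        trial = seq_len(2 * per_cell), distance_m = distance_m,
        stimulus = rep(c("left_reflector", stim_absent), each = per_cell),
        response = NA_character_)
    }) |>
    dplyr::mutate(trial = dplyr::row_number()) |>
    simulate_responses(obs, seed = 21)
  fit <- fit_sdt(trials, "categorical", chains = 2, iter = 1000,
                 warmup = 500, seed = 22)

  enc <- encode_sdt(trials)
  rates <- enc |>
    dplyr::group_by(task, distance_m) |>
    dplyr::summarise(h = mean(yes[signal == 1]), f = mean(yes[signal == 0]),
                     .groups = "drop") |>
    add_sdt_estimates(h, f)
  td <- tidy(fit)
  for (i in seq_len(nrow(rates))) {
    sel <- td$task == rates$task[i] & td$distance_m == rates$distance_m[i]
    expect_lt(abs(td$estimate[sel & td$parameter == "d_prime"] -
                    rates$d_prime[i]), 0.05)
    expect_lt(abs(td$estimate[sel & td$parameter == "criterion"] -
                    rates$criterion[i]), 0.05)
  }
})

test_that("cell log-likelihood equals the trialwise Bernoulli log-likelihood", {
  trials <- fixture_trials() |> dplyr::filter(task == "detection")
  enc <- encode_sdt(trials)
  cells <- echosdt:::aggregate_cells(enc)
  init <- echosdt:::cell_inits(cells)
  total_cells <- sum(echosdt:::cell_loglik(init$d, init$c, cells))
  # oracle: product of per-trial Bernoulli probabilities from raw 0/1 data
  dp <- init$d[match(enc$distance_m, cells$distance_m)]
  cc <- init$c[match(enc$distance_m, cells$distance_m)]
  p <- p_yes(dp, cc, enc$signal)
  total_raw <- sum(log(ifelse(enc$yes == 1, p, 1 - p)))
  expect_equal(total_cells, total_raw, tolerance = 1e-8)
})

test_that("boundary cells get finite regularized estimates with wide HPDs", {
  # all-yes hits and no false alarms: closed form undefined, posterior is not
  n <- 40
  trials <- tibble::tibble(
    participant_id = "P1", task = "detection", day = 1L, session = 1L,
    trial = seq_len(2 * n), distance_m = 1,
    stimulus = rep(c("left_reflector", "no_reflector"), each = n),
    response = rep(c("yes", "no"), each = n))
  expect_error(dprime_from_rates(1, 0), class = "echosdt_boundary_rate")
  fit <- fast_fit(trials, "categorical", seed = 31)
  td <- tidy(fit)
  expect_true(all(is.finite(td$estimate)))
  d_row <- td[td$parameter == "d_prime", ]
  expect_gt(d_row$estimate, 2) # strong but finite sensitivity
  expect_lt(d_row$estimate, 9) # within three prior SDs
  expect_gt(d_row$conf.high - d_row$conf.low, 1) # honest prior-driven width
})

test_that("empty cells and multi-participant tables are rejected", {
  trials <- fixture_trials()
  expect_error(fit_sdt(dplyr::mutate(trials,
                                     participant_id = rep(c("A", "B"),
                                                          length.out = dplyr::n())),
                       "categorical"),
               "one participant")
  # a distance present in one task only -> named empty cell
  broken <- dplyr::filter(trials,
                          !(task == "localization" & distance_m == 1.00))
  expect_error(fit_sdt(broken, "categorical"), "localization, 1.00")
  expect_error(fit_sdt(dplyr::mutate(trials, response = NA_character_),
                       "categorical"),
               "unset responses")
})

test_that("a single uninformative trial leaves the posterior near the prior", {
  trials <- tibble::tibble(
    participant_id = "P1", task = "detection", day = 1L, session = 1L,
    trial = 1:2, distance_m = 1,
    stimulus = c("left_reflector", "no_reflector"),
    response = c("yes", "no"))
  fit <- fit_sdt(trials, "categorical", chains = 2, iter = 2000,
                 warmup = 500, seed = 32)
  d_draws <- fit$draws[, grepl("dprime", colnames(fit$draws))]
  # prior sd 3; two bits of data can only sharpen it slightly
  expect_gt(stats::sd(d_draws), 1.8)
  td <- tidy(fit)
  expect_gt(max(td$conf.high - td$conf.low), 6)
})

test_that("a flat-sensitivity truth yields a rate posterior centered at 0", {
  obs <- observer_exponential(1.5, 0, 1.5, 0, 0, 0) # d' constant in distance
  design <- echo_design(distances_m = c(1, 2, 3, 4), days = 2,
                        sessions_per_day = 5)
  trials <- simulate_experiment(design, obs, participants = "P1",
                                seed = 33) |>
    analysis_subset(design)
  fit <- fast_fit(trials, "exponential", seed = 34)
  td <- tidy(fit)
  a1 <- td[td$term == "alpha1", ]
  expect_lte(a1$conf.low, 0)
  expect_gte(a1$conf.high, 0)
})

test_that("categorical and exponential fits agree when truth is exponential", {
  fc <- fixture_fit("categorical")
  fe <- fixture_fit("exponential")
  curve <- predict_dprime(fe, distance_m = echo_design()$distances_m)
  cat_est <- predict_dprime(fc)
  joined <- dplyr::inner_join(cat_est, curve, by = c("task", "distance_m"),
                              suffix = c(".cat", ".exp"))
  # cell medians should fall inside the union of the two 95% intervals
  # at nearly every distance when the generative model is the fitted curve
  inside <- joined$estimate.cat >=
    pmin(joined$conf.low.exp, joined$conf.low.cat) &
    joined$estimate.cat <= pmax(joined$conf.high.exp, joined$conf.high.cat)
  expect_gte(mean(inside), 0.9)
  expect_lt(mean(abs(joined$estimate.cat - joined$estimate.exp)), 0.35)
})
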