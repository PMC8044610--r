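test_that("HPD interval is the narrowest window and is order-invariant", {
  set.seed(1)
  x <- rnorm(1e5)
  h <- hpd_interval(x)
  expect_equal(h[["lower"]], -1.96, tolerance = 0.03)
  expect_equal(h[["upper"]], 1.96, tolerance = 0.03)
  expect_identical(hpd_interval(sample(x)), h)
  # flat density: any 95% window works, width pinned at 0.95
  u <- runif(1e5)
  hu <- hpd_interval(u)
  expect_equal(hu[["upper"]] - hu[["lower"]], 0.95, tolerance = 0.01)
  # skewed density: HPD must beat the equal-tails interval and contain the mode
  g <- rgamma(1e5, shape = 2, rate = 1)
  hg <- hpd_interval(g)
  et <- quantile(g, c(0.025, 0.975))
  expect_lt(hg[["upper"]] - hg[["lower"]], et[[2]] - et[[1]])
  expect_lt(hg[["lower"]], 1) # mode of gamma(2,1)
  expect_gt(hg[["upper"]], 1)
})

test_that("HPD interval handles degenerate and invalid input", {
  expect_equal(unname(hpd_interval(rep(5, 200))), c(5, 5))
  expect_error(hpd_interval(rnorm(50)), "at least 100")
  expect_error(hpd_interval(rnorm(200), mass = 1.2), "between 0 and 1")
  expect_error(hpd_interval(c(rnorm(200), NA)), "NA")
})

test_that("split-Rhat and ESS diagnose mixing correctly", {
  set.seed(2)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(echosdt:::split_rhat(iid), 1.01)
  expect_gt(echosdt:::ess_basic(iid), 3000)
  # chains stuck at different levels
  apart <- iid + rep(c(0, 0, 3, 3), each = 1000)
  expect_gt(echosdt:::split_rhat(apart), 1.5)
  # a trending chain is caught by the split in split-Rhat
  trend <- matrix(rnorm(4000), 1000, 4) + seq(0, 3, length.out = 1000)
  expect_gt(echosdt:::split_rhat(trend), 1.1)
  # strong autocorrelation shrinks ESS
  ar <- matrix(0, 1000, 4)
  for (ch in 1:4) {
    e <- rnorm(1000)
    for (t in 2:1000) ar[t, ch] <- 0.95 * ar[t - 1, ch] + e[t]
  }
  expect_lt(echosdt:::ess_basic(ar), 500)
})

test_that("the sampler reproduces the prior when the likelihood is flat", {
  prior_only <- function(th) sum(stats::dnorm(th, 0, 3, log = TRUE))
  res <- echosdt:::rwm_sample(prior_only, init = c(0, 0), chol_L = diag(2),
                    n_warmup = 500, n_keep = 2000, chains = 4, seed = 3)
  flat <- matrix(res$draws, ncol = 2)
  expect_equal(mean(flat[, 1]), 0, tolerance = 0.2)
  expect_equal(stats::sd(flat[, 1]), 3, tolerance = 0.2)
  expect_equal(mean(flat[, 2]), 0, tolerance = 0.2)
  expect_equal(stats::sd(flat[, 2]), 3, tolerance = 0.2)
})

test_that("posterior medians match grid quadrature on single-cell data", {
  # one detection cell: 90/120 hits, 30/110 false alarms
  counts <- list(n1 = 120, k1 = 90, n0 = 110, k0 = 30)
  oracle <- oracle_cell_medians(counts$n1, counts$k1, counts$n0, counts$k0)
  trials <- tibble::tibble(
    participant_id = "P1", task = "detection", day = 1L, session = 1L,
    trial = seq_len(counts$n1 + counts$n0), distance_m = 2,
    stimulus = rep(c("left_reflector", "no_reflector"),
                   c(counts$n1, counts$n0)),
    response = c(rep(c("yes", "no"), c(counts$k1, counts$n1 - counts$k1)),
                 rep(c("yes", "no"), c(counts$k0, counts$n0 - counts$k0))))
  fit <- fit_sdt(trials, "categorical", chains = 4, iter = 2000,
                 warmup = 500, seed = 4)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$parameter == "d_prime"] - oracle[["d"]]), 0.02)
  expect_lt(abs(td$estimate[td$parameter == "criterion"] - oracle[["c"]]),
            0.02)
})

test_that("sampling is deterministic given the seed", {
  trials <- fixture_trials() |>
    dplyr::filter(task == "detection", distance_m < 2)
  a <- fast_fit(trials, "categorical", seed = 11)
  b <- fast_fit(trials, "categorical", seed = 11)
  expect_identical(a$draws, b$draws)
  c_ <- fast_fit(trials, "categorical", seed = 12)
  expect_false(identical(a$draws, c_$draws))
})
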