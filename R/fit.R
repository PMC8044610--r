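#' Bayesian SDT models for one participant
#'
#' Fits one of two Bernoulli-probit signal detection models to the trial-level
#' data of a single participant, by MCMC with independent weakly informative
#' Normal(0, 3) priors on every parameter:
#'
#' * **categorical** — d' and c estimated separately for each task and each
#'   distance (distance treated as a categorical variable). With 2 tasks and
#'   10 distances this is the 40-parameter model whose per-cell estimates are
#'   treated as the "observed" sensitivities.
#' * **exponential** — d' is an exponential function of distance within task,
#'   `d'(x) = a0 exp(a1 x)` for detection and `b0 exp(b1 x)` for localization,
#'   with one distance-constant criterion per task (`c0`, `c1`): 6 parameters.
#'
#' Both models use the observation law of [p_yes()]: each response is an
#' independent Bernoulli trial whose probability depends on the trial's
#' signal coding (see [encode_sdt()]). Unlike the closed-form estimators, the
#' Bayesian fits remain defined when a cell has all-yes or all-no responses:
#' the prior regularizes the estimate (with an honestly wide interval).
#'
#' Sampling uses an adaptive random-walk Metropolis sampler initialized at
#' the posterior mode with a Hessian-based proposal covariance. Convergence
#' is assessed with split-\eqn{\hat R} and effective sample size; a fit is
#' marked converged when every parameter has \eqn{\hat R \le 1.01} and
#' ESS \eqn{\ge 400}. A fit with \eqn{\hat R > 1.01} triggers a warning —
#' never a silent success.
#'
#' @param trials Trial tibble for one participant with responses set (both
#'   tasks for the standard models).
#' @param model `"categorical"` or `"exponential"`.
#' @param chains Number of MCMC chains (default 4).
#' @param iter Post-warmup draws per chain (default 1500).
#' @param warmup Warmup (adaptation) iterations per chain (default 1000).
#' @param seed Integer seed; fits are deterministic given seed and config.
#' @param mass Probability mass of the reported HPD intervals (default 0.95).
#' @return An object of class `sdt_fit`; see [tidy.sdt_fit()],
#'   [glance.sdt_fit()], [posterior_draws()], [autoplot.sdt_fit()].
#' @examples
#' \donttest{
#' design <- echo_design(distances_m = c(1, 2.5), days = 2,
#'                       sessions_per_day = 2, practice_days = 1)
#' obs <- observer_exponential(3, -0.4, 2, -0.6, 0.1, -0.2)
#' trials <- simulate_experiment(design, obs, participants = "P1", seed = 1) |>
#'   analysis_subset(design)
#' fit <- fit_sdt(trials, "categorical", chains = 2, iter = 400,
#'                warmup = 400, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_sdt <- function(trials, model = c("categorical", "exponential"),
                    chains = 4L, iter = 1500L, warmup = 1000L,
                    seed = 1L, mass = 0.95) {
  model <- match.arg(model)
  trials <- encode_sdt(trials)
  pid <- unique(trials$participant_id)
  if (length(pid) != 1) {
    stop("fit_sdt() fits one participant at a time; got: ",
         paste(pid, collapse = ", "), ". Use fit_participants().",
         call. = FALSE)
  }
  if (anyNA(trials$yes)) {
    stop("trials contain unset responses; simulate or load responses first",
         call. = FALSE)
  }

  cells <- aggregate_cells(trials)
  check_cells(cells)

  fitted <- if (model == "categorical") {
    fit_categorical_cells(cells, chains, iter, warmup, seed)
  } else {
    fit_exponential_cells(trials, cells, chains, iter, warmup, seed)
  }

  summarize_fit(fitted, model = model, participant_id = pid,
                n_trials = nrow(trials), cells = cells,
                chains = chains, iter = iter, warmup = warmup,
                seed = seed, mass = mass)
}

#' Fit both models to every participant in a trial table
#'
#' @param trials Trial tibble (any number of participants).
#' @param model `"categorical"`, `"exponential"`, or `"both"`.
#' @inheritParams fit_sdt
#' @return A named list (by participant) of lists of `sdt_fit` objects.
#' @export
fit_participants <- function(trials, model = "both", chains = 4L,
                             iter = 1500L, warmup = 1000L, seed = 1L,
                             mass = 0.95) {
  model <- match.arg(model, c("categorical", "exponential", "both"))
  models <- if (model == "both") c("categorical", "exponential") else model
  trials <- tibble::as_tibble(trials)
  pids <- unique(trials$participant_id)
  out <- purrr::map(pids, function(pid) {
    sub <- dplyr::filter(trials, .data$participant_id == pid)
    purrr::map(stats::setNames(models, models), function(m) {
      fit_sdt(sub, m, chains = chains, iter = iter, warmup = warmup,
              seed = derive_seed(seed, "fit", pid, m), mass = mass)
    })
  })
  stats::setNames(out, pids)
}

# ---- data aggregation -------------------------------------------------------

# One row per (task, distance): counts of yes-responses among signal-present
# (hits) and signal-absent (false alarms) trials. The Bernoulli likelihood
# collapses exactly onto these binomial counts (no choose() constant is
# carried, so cell log-likelihoods equal the sum of trialwise log p_i).
aggregate_cells <- function(encoded) {
  encoded |>
    dplyr::group_by(.data$task, .data$distance_m) |>
    dplyr::summarise(
      n1 = sum(.data$signal == 1L),
      k1 = sum(.data$yes[.data$signal == 1L]),
      n0 = sum(.data$signal == 0L),
      k0 = sum(.data$yes[.data$signal == 0L]),
      .groups = "drop") |>
    dplyr::arrange(factor(.data$task, levels = task_labels),
                   .data$distance_m)
}

check_cells <- function(cells) {
  full <- tidyr::expand_grid(task = unique(cells$task),
                             distance_m = unique(cells$distance_m))
  missing <- dplyr::anti_join(full, cells, by = c("task", "distance_m"))
  empty <- dplyr::filter(cells, .data$n1 + .data$n0 == 0)
  bad <- dplyr::bind_rows(missing, empty[, c("task", "distance_m")])
  if (nrow(bad)) {
    stop("no trials in cell(s): ",
         paste(sprintf("(%s, %.2f m)", bad$task, bad$distance_m),
               collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

clamp_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# Per-cell binomial log-likelihood at (d', c); vectorized over cells.
cell_loglik <- function(d_prime, criterion, cells) {
  p1 <- clamp_p(1 - stats::pnorm(criterion - d_prime / 2))
  p0 <- clamp_p(1 - stats::pnorm(criterion + d_prime / 2))
  cells$k1 * log(p1) + (cells$n1 - cells$k1) * log(1 - p1) +
    cells$k0 * log(p0) + (cells$n0 - cells$k0) * log(1 - p0)
}

prior_sd <- 3

# Adjusted (never-boundary) rate-based starting values per cell.
cell_inits <- function(cells) {
  H <- (cells$k1 + 0.5) / (cells$n1 + 1)
  F_ <- (cells$k0 + 0.5) / (cells$n0 + 1)
  list(d = stats::qnorm(H) - stats::qnorm(F_),
       c = -(stats::qnorm(H) + stats::qnorm(F_)) / 2)
}

# ---- categorical model ------------------------------------------------------

fit_categorical_cells <- function(cells, chains, iter, warmup, seed) {
  K <- nrow(cells)
  logpost_DC <- function(D, C) {
    cell_loglik(D, C, cells) +
      stats::dnorm(D, 0, prior_sd, log = TRUE) +
      stats::dnorm(C, 0, prior_sd, log = TRUE)
  }

  init <- cell_inits(cells)
  r11 <- r21 <- r22 <- numeric(K)
  map_D <- init$d
  map_C <- init$c
  for (j in seq_len(K)) {
    cj <- cells[j, ]
    nlp <- function(th) -(cell_loglik(th[1], th[2], cj) +
                            sum(stats::dnorm(th, 0, prior_sd, log = TRUE)))
    opt <- tryCatch(
      stats::optim(c(init$d[j], init$c[j]), nlp, method = "BFGS",
                   hessian = TRUE),
      error = function(e) NULL)
    L <- NULL
    if (!is.null(opt) && all(is.finite(opt$par))) {
      map_D[j] <- opt$par[1]
      map_C[j] <- opt$par[2]
      L <- tryCatch(t(chol(solve(opt$hessian))), error = function(e) NULL)
    }
    if (is.null(L)) L <- diag(c(0.3, 0.2))
    r11[j] <- L[1, 1]; r21[j] <- L[2, 1]; r22[j] <- L[2, 2]
  }

  res <- rwm_sample_cells(logpost_DC, map_D, map_C, r11, r21, r22,
                          n_warmup = warmup, n_keep = iter,
                          chains = chains, seed = seed)

  terms <- tibble::tibble(
    term = c(sprintf("dprime[%s,%.2f]", cells$task, cells$distance_m),
             sprintf("c[%s,%.2f]", cells$task, cells$distance_m)),
    parameter = rep(c("d_prime", "criterion"), each = K),
    task = rep(cells$task, 2),
    distance_m = rep(cells$distance_m, 2))

  draws_array <- array(NA_real_, dim = c(iter, chains, 2 * K),
                       dimnames = list(NULL, NULL, terms$term))
  draws_array[, , seq_len(K)] <- res$draws_D
  draws_array[, , K + seq_len(K)] <- res$draws_C
  list(draws_array = draws_array, terms = terms,
       accept = mean(res$accept))
}

# ---- exponential model ------------------------------------------------------

expo_terms <- c("alpha0", "alpha1", "beta0", "beta1", "c0", "c1")

# d' and c implied by the 6-vector theta at given task/distance vectors.
expo_curve <- function(theta, task, distance_m) {
  loc <- task == "localization"
  d <- ifelse(loc, theta[3] * exp(theta[4] * distance_m),
              theta[1] * exp(theta[2] * distance_m))
  c_ <- ifelse(loc, theta[6], theta[5])
  list(d = d, c = c_)
}

expo_loglik <- function(theta, cells) {
  cur <- expo_curve(theta, cells$task, cells$distance_m)
  sum(cell_loglik(cur$d, cur$c, cells))
}

fit_exponential_cells <- function(trials, cells, chains, iter, warmup, seed) {
  logpost <- function(theta) {
    expo_loglik(theta, cells) +
      sum(stats::dnorm(theta, 0, prior_sd, log = TRUE))
  }

  init <- expo_init(cells)
  nlp <- function(th) -logpost(th)
  opt <- tryCatch(stats::optim(init, nlp, method = "BFGS", hessian = TRUE,
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  map <- init
  L <- NULL
  if (!is.null(opt) && all(is.finite(opt$par))) {
    map <- opt$par
    L <- tryCatch(t(chol(solve(opt$hessian))), error = function(e) NULL)
  }
  if (is.null(L)) L <- diag(0.2, 6)

  res <- rwm_sample(logpost, map, L, n_warmup = warmup, n_keep = iter,
                    chains = chains, seed = seed)

  terms <- tibble::tibble(
    term = expo_terms,
    parameter = c("amplitude", "rate", "amplitude", "rate",
                  "criterion", "criterion"),
    task = c("detection", "detection", "localization", "localization",
             "detection", "localization"),
    distance_m = NA_real_)
  dimnames(res$draws)[[3]] <- expo_terms
  list(draws_array = res$draws, terms = terms, accept = mean(res$accept))
}

# Rough exponential-curve start: log-linear regression on positive adjusted
# per-cell d' estimates; flat curve at the mean |d'| otherwise.
expo_init <- function(cells) {
  init <- cell_inits(cells)
  theta <- c(1, 0, 1, 0, 0, 0)
  for (tk in c("detection", "localization")) {
    i <- cells$task == tk
    off <- if (tk == "detection") 0 else 2
    d <- init$d[i]; x <- cells$distance_m[i]
    pos <- d > 0.05
    if (sum(pos) >= 2 && length(unique(x[pos])) >= 2) {
      co <- stats::coef(stats::lm(log(d[pos]) ~ x[pos]))
      theta[off + 1] <- min(exp(co[1]), 8)
      theta[off + 2] <- max(min(co[2], 2), -3)
    } else {
      theta[off + 1] <- max(mean(d), 0.1)
      theta[off + 2] <- 0
    }
    theta[if (tk == "detection") 5 else 6] <- mean(init$c[i])
  }
  theta
}

# ---- summaries and methods --------------------------------------------------

summarize_fit <- function(fitted, model, participant_id, n_trials, cells,
                          chains, iter, warmup, seed, mass) {
  arr <- fitted$draws_array
  P <- dim(arr)[3]
  terms <- fitted$terms
  flat <- matrix(arr, nrow = dim(arr)[1] * dim(arr)[2], ncol = P,
                 dimnames = list(NULL, terms$term))

  summ <- purrr::map_dfr(seq_len(P), function(p) {
    dr <- flat[, p]
    hpd <- hpd_interval(dr, mass)
    tibble::tibble(
      estimate = stats::median(dr),
      conf.low = hpd[["lower"]],
      conf.high = hpd[["upper"]],
      rhat = split_rhat(arr[, , p, drop = TRUE]),
      ess = ess_basic(arr[, , p, drop = TRUE]))
  })
  summary <- dplyr::bind_cols(terms, summ)

  max_rhat <- max(summary$rhat)
  min_ess <- min(summary$ess)
  converged <- is.finite(max_rhat) && max_rhat <= 1.01 && min_ess >= 400
  if (!is.finite(max_rhat) || max_rhat > 1.01) {
    warning("fit for participant ", participant_id, " (", model,
            " model) did not converge: max split-Rhat = ",
            format(max_rhat, digits = 4), call. = FALSE)
  }

  structure(
    list(model = model, participant_id = participant_id,
         draws = flat, draws_array = arr, summary = summary, mass = mass,
         cells = cells, converged = converged,
         meta = list(chains = chains, iter = iter, warmup = warmup,
                     seed = seed, accept = fitted$accept,
                     n_trials = n_trials, max_rhat = max_rhat,
                     min_ess = min_ess)),
    class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat(sprintf("<sdt_fit: %s model, participant %s>\n", x$model,
              x$participant_id))
  cat(sprintf("  %d trials; %d parameters; %d chains x %d draws (warmup %d)\n",
              x$meta$n_trials, nrow(x$summary), x$meta$chains, x$meta$iter,
              x$meta$warmup))
  cat(sprintf("  converged: %s (max Rhat %.3f, min ESS %.0f)\n",
              x$converged, x$meta$max_rhat, x$meta$min_ess))
  print(x$summary, n = min(nrow(x$summary), 12))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summary of an SDT fit
#'
#' One row per model parameter: posterior median (`estimate`), HPD interval
#' bounds (`conf.low`, `conf.high`), split-Rhat and effective sample size.
#'
#' @param x An `sdt_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `parameter`, `task`, `distance_m`,
#'   `estimate`, `conf.low`, `conf.high`, `rhat`, `ess`.
#' @method tidy sdt_fit
#' @export
tidy.sdt_fit <- function(x, ...) {
  x$summary
}

#' One-row fit overview
#'
#' @param x An `sdt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, participant, trial and parameter counts,
#'   sampler settings, worst diagnostics, convergence flag.
#' @method glance sdt_fit
#' @export
glance.sdt_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    participant_id = x$participant_id,
    n_trials = x$meta$n_trials,
    n_parameters = nrow(x$summary),
    chains = x$meta$chains,
    iter = x$meta$iter,
    max_rhat = x$meta$max_rhat,
    min_ess = x$meta$min_ess,
    converged = x$converged)
}

#' Posterior draws as a tibble
#'
#' @param fit An `sdt_fit`.
#' @return A tibble with `.chain`, `.iteration` and one column per parameter.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "sdt_fit"))
  arr <- fit$draws_array
  n <- dim(arr)[1]; m <- dim(arr)[2]
  out <- tibble::as_tibble(fit$draws)
  dplyr::bind_cols(
    tibble::tibble(.chain = rep(seq_len(m), each = n),
                   .iteration = rep(seq_len(n), m)),
    out)
}

#' Posterior d' over distance implied by a fit
#'
#' For a categorical fit, the per-distance posterior summaries; for an
#' exponential fit, the fitted curve `amplitude * exp(rate * x)` evaluated
#' draw-wise over `distance_m` and summarized by median and HPD interval.
#'
#' @param fit An `sdt_fit`.
#' @param distance_m Evaluation grid (defaults to the fitted distances, or
#'   a fine grid over their range for the exponential model).
#' @param mass HPD mass.
#' @return Tibble with `task`, `distance_m`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
predict_dprime <- function(fit, distance_m = NULL, mass = fit$mass) {
  stopifnot(inherits(fit, "sdt_fit"))
  if (fit$model == "categorical") {
    out <- dplyr::filter(fit$summary, .data$parameter == "d_prime")
    return(dplyr::select(out, "task", "distance_m", "estimate",
                         "conf.low", "conf.high"))
  }
  if (is.null(distance_m)) {
    rng <- range(fit$cells$distance_m)
    distance_m <- seq(rng[1], rng[2], length.out = 50)
  }
  dr <- fit$draws
  purrr::map_dfr(c("detection", "localization"), function(tk) {
    a <- if (tk == "detection") dr[, "alpha0"] else dr[, "beta0"]
    r <- if (tk == "detection") dr[, "alpha1"] else dr[, "beta1"]
    purrr::map_dfr(distance_m, function(x) {
      v <- a * exp(r * x)
      hpd <- hpd_interval(v, mass)
      tibble::tibble(task = tk, distance_m = x,
                     estimate = stats::median(v),
                     conf.low = hpd[["lower"]], conf.high = hpd[["upper"]])
    })
  })
}
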