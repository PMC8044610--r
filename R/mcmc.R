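#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws — the conventional HPD summary for a unimodal marginal
#' posterior, reported alongside the posterior median throughout the
#' package.
#'
#' @param samples Numeric vector of posterior draws (at least 100).
#' @param mass Probability mass of the interval, in (0, 1). Default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e4))
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (length(mass) != 1 || !is.finite(mass) || mass <= 0 || mass >= 1) {
    stop("`mass` must be a single probability strictly between 0 and 1",
         call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("`samples` contains NA", call. = FALSE)
  n <- length(samples)
  m <- ceiling(mass * n)
  if (n < 100) {
    stop("need at least 100 draws for an HPD interval (got ", n, ")",
         call. = FALSE)
  }
  sorted <- sort(samples)
  widths <- sorted[m:n] - sorted[1:(n - m + 1)]
  nw <- length(widths)
  # the raw argmin is noisy because the width profile is nearly flat around
  # its minimum; minimizing a locally averaged width stabilizes the window
  # position without changing what is being estimated
  k <- min(nw, max(1L, floor(nw / 10)))
  if (k > 1) {
    cs <- cumsum(c(0, widths))
    lo <- pmax(1L, seq_len(nw) - k)
    hi <- pmin(nw, seq_len(nw) + k)
    widths <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  i <- which.min(widths)
  c(lower = sorted[i], upper = sorted[i + m - 1])
}

# ---- Convergence diagnostics ------------------------------------------------

# draws: iterations x chains matrix for one parameter.
# Split-Rhat: each chain is halved, then the classical potential scale
# reduction factor is computed on the 2m half-chains.
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[seq.int(n - half + 1, n), , drop = FALSE])
}

split_rhat <- function(draws) {
  x <- split_chains(draws)
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (!is.finite(W) || W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# Effective sample size across chains, Geyer initial-monotone-sequence
# truncation on paired autocorrelation sums.
ess_basic <- function(draws) {
  x <- split_chains(draws)
  n <- nrow(x)
  m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  if (!is.finite(W) || W == 0) return(m * n)
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n

  max_lag <- min(n - 2, 1000L)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov) # index 1 = lag 0
  rho <- 1 - (W - mean_acov[-1]) / var_plus # lags 1..max_lag
  rho <- c(1, rho)                          # prepend lag 0

  # pair sums P_k = rho_{2k} + rho_{2k+1}
  n_pairs <- floor(length(rho) / 2)
  P <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  neg <- which(P <= 0)
  if (length(neg)) P <- P[seq_len(neg[1] - 1)]
  if (length(P) == 0) return(m * n)
  P <- cummin(P) # enforce monotone decrease
  tau <- max(2 * sum(P) - 1, 1 / (m * n))
  min(m * n, m * n / tau)
}

# ---- Adaptive random-walk Metropolis ---------------------------------------

# Generic d-dimensional sampler. log_post takes a parameter vector and
# returns a scalar log posterior density (up to a constant). chol_L is a
# lower-triangular factor of the proposal covariance shape (typically from
# the inverse Hessian at the MAP); the global step scale is adapted during
# warmup towards the dimension-appropriate acceptance rate, with one
# covariance re-estimation halfway through warmup.
rwm_sample <- function(log_post, init, chol_L, n_warmup = 1000L,
                       n_keep = 1000L, chains = 4L, seed = 1L,
                       target_accept = NULL) {
  d <- length(init)
  if (is.null(target_accept)) target_accept <- if (d <= 2) 0.35 else 0.234
  draws <- array(NA_real_, dim = c(n_keep, chains, d))
  accept <- numeric(chains)

  for (ch in seq_len(chains)) {
    s <- derive_seed(seed, "rwm-chain", ch)
    res <- withr::with_seed(s, {
      L <- chol_L
      ls <- 0 # log of scale multiplier on top of 2.38/sqrt(d)
      base <- 2.38 / sqrt(d)
      x <- init + base * as.numeric(L %*% stats::rnorm(d))
      lp <- log_post(x)
      if (!is.finite(lp)) { x <- init; lp <- log_post(x) }
      # after warmup, a short tuning segment runs the mixture kernel and
      # refits the independence proposal from its (better-mixing) draws
      # before any draw is kept
      n_tune <- min(500L, n_warmup)
      warm_store <- matrix(NA_real_, n_warmup + n_tune, d)
      keep <- matrix(NA_real_, n_keep, d)
      n_acc <- 0L
      n_adapt <- n_warmup + n_tune
      total <- n_adapt + n_keep
      # covariance re-estimation points: windows over warmup, each using the
      # draws since the previous update
      recov_at <- unique(floor(n_warmup * c(0.25, 0.5, 1)))
      recov_at <- recov_at[recov_at >= max(50, 5 * d)]
      last_win <- 1L
      t_adapt <- 0L
      # independence-proposal parameters, fitted at the end of warmup
      df_t <- 4
      mu_q <- NULL; L_q <- NULL; ldt_x <- NULL
      ldt <- function(v) {
        u <- forwardsolve(L_q, v - mu_q)
        -0.5 * (df_t + d) * log1p(sum(u^2) / df_t)
      }
      recov_at <- c(recov_at, n_adapt)
      for (t in seq_len(total)) {
        use_imh <- t > n_warmup && !is.null(L_q) && stats::runif(1) > 0.25
        if (use_imh) {
          w <- sqrt(df_t / stats::rchisq(1, df_t))
          prop <- mu_q + as.numeric(L_q %*% stats::rnorm(d)) * w
          lp_prop <- log_post(prop)
          ldt_prop <- ldt(prop)
          a <- if (is.finite(lp_prop)) {
            min(1, exp(lp_prop - lp + ldt_x - ldt_prop))
          } else 0
        } else {
          step <- exp(ls) * base
          prop <- x + step * as.numeric(L %*% stats::rnorm(d))
          lp_prop <- log_post(prop)
          a <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
        }
        moved <- stats::runif(1) < a
        if (moved) {
          x <- prop; lp <- lp_prop
          if (!is.null(L_q)) ldt_x <- if (use_imh) ldt_prop else ldt(x)
        }
        if (t <= n_adapt) {
          warm_store[t, ] <- x
          t_adapt <- t_adapt + 1L
          ls <- ls + t_adapt^(-0.6) * (a - target_accept)
          if (t %in% recov_at) {
            win <- seq.int(last_win, t)
            S <- stats::cov(warm_store[win, , drop = FALSE])
            Lnew <- tryCatch(t(chol(S + diag(1e-10, d))),
                             error = function(e) NULL)
            if (!is.null(Lnew)) { L <- Lnew; ls <- 0; t_adapt <- 0L }
            last_win <- t
            if (t >= n_warmup && !is.null(Lnew)) {
              # (re)fit the mixture kernel: heavy-tailed independence
              # proposal around the posterior shape + residual random walks
              mu_q <- colMeans(warm_store[win, , drop = FALSE])
              L_q <- Lnew
              ldt_x <- ldt(x)
            }
          }
        } else {
          keep[t - n_adapt, ] <- x
          if (moved) n_acc <- n_acc + 1L
        }
      }
      list(keep = keep, acc = n_acc / n_keep)
    })
    draws[, ch, ] <- res$keep
    accept[ch] <- res$acc
  }
  list(draws = draws, accept = accept)
}

# Vectorized sampler for K independent 2-D posteriors (the categorical
# model's per-cell (d', c) pairs): all cells advance in one R-level loop.
# loglik_DC(D, C) must return a length-K vector of cell log posteriors.
# L components are per-cell lower-triangular factors: dx1 = r11 z1,
# dx2 = r21 z1 + r22 z2.
rwm_sample_cells <- function(loglik_DC, init_D, init_C, r11, r21, r22,
                             n_warmup = 1000L, n_keep = 1000L, chains = 4L,
                             seed = 1L, target_accept = 0.35) {
  K <- length(init_D)
  draws_D <- array(NA_real_, dim = c(n_keep, chains, K))
  draws_C <- array(NA_real_, dim = c(n_keep, chains, K))
  accept <- matrix(0, chains, K)
  base <- 2.38 / sqrt(2)

  for (ch in seq_len(chains)) {
    s <- derive_seed(seed, "rwm-cells-chain", ch)
    res <- withr::with_seed(s, {
      ls <- rep(0, K)
      z1 <- stats::rnorm(K); z2 <- stats::rnorm(K)
      D <- init_D + base * r11 * z1
      C <- init_C + base * (r21 * z1 + r22 * z2)
      lp <- loglik_DC(D, C)
      bad <- !is.finite(lp)
      if (any(bad)) { D[bad] <- init_D[bad]; C[bad] <- init_C[bad]
                      lp <- loglik_DC(D, C) }
      kD <- matrix(NA_real_, n_keep, K)
      kC <- matrix(NA_real_, n_keep, K)
      wD <- matrix(NA_real_, n_warmup, K)
      wC <- matrix(NA_real_, n_warmup, K)
      n_acc <- rep(0L, K)
      total <- n_warmup + n_keep
      recov_at <- unique(floor(n_warmup * c(0.25, 0.5, 1)))
      recov_at <- recov_at[recov_at >= 50]
      last_win <- 1L
      t_adapt <- 0L
      # per-cell independence-t proposal, fitted at the end of warmup
      df_t <- 4
      has_q <- rep(FALSE, K)
      muD <- muC <- q11 <- q21 <- q22 <- rep(NA_real_, K)
      ldt_cells <- function(Dv, Cv) {
        u1 <- (Dv - muD) / q11
        u2 <- ((Cv - muC) - q21 * u1) / q22
        out <- -0.5 * (df_t + 2) * log1p((u1^2 + u2^2) / df_t)
        out[!has_q] <- 0
        out
      }
      ldt_cur <- rep(0, K)
      for (t in seq_len(total)) {
        z1 <- stats::rnorm(K); z2 <- stats::rnorm(K)
        imh <- if (t > n_warmup) has_q & (stats::runif(K) > 0.25) else
          rep(FALSE, K)
        step <- exp(ls) * base
        Dp <- D + step * r11 * z1
        Cp <- C + step * (r21 * z1 + r22 * z2)
        corr <- rep(0, K)
        if (any(imh)) {
          w <- sqrt(df_t / stats::rchisq(K, df_t))
          Dq <- muD + q11 * z1 * w
          Cq <- muC + (q21 * z1 + q22 * z2) * w
          Dp[imh] <- Dq[imh]; Cp[imh] <- Cq[imh]
          ldt_prop <- ldt_cells(Dp, Cp)
          corr[imh] <- ldt_cur[imh] - ldt_prop[imh]
        }
        lpp <- loglik_DC(Dp, Cp)
        a <- exp(pmin(0, lpp - lp + corr))
        a[!is.finite(lpp)] <- 0
        acc <- stats::runif(K) < a
        D[acc] <- Dp[acc]; C[acc] <- Cp[acc]; lp[acc] <- lpp[acc]
        if (any(has_q) && any(acc)) {
          ldt_new <- ldt_cells(D, C)
          ldt_cur[acc] <- ldt_new[acc]
        }
        if (t <= n_warmup) {
          wD[t, ] <- D; wC[t, ] <- C
          t_adapt <- t_adapt + 1L
          ls <- ls + t_adapt^(-0.6) * (a - target_accept)
          if (t %in% recov_at) {
            win <- seq.int(last_win, t)
            final <- t == max(recov_at)
            for (j in seq_len(K)) {
              S <- stats::cov(cbind(wD[win, j], wC[win, j]))
              Lj <- tryCatch(t(chol(S + diag(1e-10, 2))),
                             error = function(e) NULL)
              if (!is.null(Lj)) {
                r11[j] <- Lj[1, 1]; r21[j] <- Lj[2, 1]; r22[j] <- Lj[2, 2]
                ls[j] <- 0
                if (final) {
                  muD[j] <- mean(wD[win, j]); muC[j] <- mean(wC[win, j])
                  q11[j] <- Lj[1, 1]; q21[j] <- Lj[2, 1]; q22[j] <- Lj[2, 2]
                  has_q[j] <- TRUE
                }
              }
            }
            t_adapt <- 0L
            last_win <- t
            if (final && any(has_q)) ldt_cur <- ldt_cells(D, C)
          }
        } else {
          kD[t - n_warmup, ] <- D
          kC[t - n_warmup, ] <- C
          n_acc <- n_acc + acc
        }
      }
      list(kD = kD, kC = kC, acc = n_acc / n_keep)
    })
    draws_D[, ch, ] <- res$kD
    draws_C[, ch, ] <- res$kC
    accept[ch, ] <- res$acc
  }
  list(draws_D = draws_D, draws_C = draws_C, accept = accept)
}
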