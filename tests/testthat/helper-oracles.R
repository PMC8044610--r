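# Independent oracles used to validate the package's own code paths.

# Normal CDF by numerical integration of the density (independent of pnorm).
oracle_phi <- function(x) {
  0.5 + stats::integrate(stats::dnorm, 0, x, rel.tol = 1e-12)$value
}

# Inverse normal CDF by bisection on oracle_phi (independent of qnorm).
oracle_phi_inv <- function(p) {
  lo <- -10; hi <- 10
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (oracle_phi(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Posterior medians of (d', c) for a single binomial cell under the
# Bernoulli-probit SDT likelihood with Normal(0, 3) priors, by dense 2-D
# grid quadrature — an MCMC-free reference for the sampler.
oracle_cell_medians <- function(n1, k1, n0, k0, lim = 8, ngrid = 801) {
  d <- seq(-lim, lim, length.out = ngrid)
  cc <- seq(-lim / 2, lim / 2, length.out = ngrid)
  D <- matrix(d, ngrid, ngrid)
  C <- matrix(cc, ngrid, ngrid, byrow = TRUE)
  p1 <- pmin(pmax(1 - stats::pnorm(C - D / 2), 1e-12), 1 - 1e-12)
  p0 <- pmin(pmax(1 - stats::pnorm(C + D / 2), 1e-12), 1 - 1e-12)
  ll <- k1 * log(p1) + (n1 - k1) * log(1 - p1) +
    k0 * log(p0) + (n0 - k0) * log(1 - p0) +
    stats::dnorm(D, 0, 3, log = TRUE) + stats::dnorm(C, 0, 3, log = TRUE)
  w <- exp(ll - max(ll))
  wmed <- function(x, wts) {
    cw <- cumsum(wts) / sum(wts)
    stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
  }
  c(d = wmed(d, rowSums(w)), c = wmed(cc, colSums(w)))
}

# Brute-force two-way within-subject ANOVA from the defining sums of
# squares (independent of stats::aov).
oracle_rm_anova <- function(grid) {
  y <- stats::xtabs(d_prime ~ participant_id + task + distance_m, grid)
  n <- dim(y)[1]; tt <- dim(y)[2]; k <- dim(y)[3]
  gm <- mean(y)
  m_s <- apply(y, 1, mean); m_t <- apply(y, 2, mean); m_d <- apply(y, 3, mean)
  m_st <- apply(y, c(1, 2), mean)
  m_sd <- apply(y, c(1, 3), mean)
  m_td <- apply(y, c(2, 3), mean)

  ss_task <- n * k * sum((m_t - gm)^2)
  ss_dist <- n * tt * sum((m_d - gm)^2)
  ss_subj <- tt * k * sum((m_s - gm)^2)
  ss_task_subj <- k * sum((m_st - outer(m_s, rep(1, tt)) -
                             outer(rep(1, n), m_t) + gm)^2)
  ss_dist_subj <- tt * sum((m_sd - outer(m_s, rep(1, k)) -
                              outer(rep(1, n), m_d) + gm)^2)
  ss_td <- n * sum((m_td - outer(m_t, rep(1, k)) -
                      outer(rep(1, tt), m_d) + gm)^2)
  resid <- y
  for (i in 1:n) for (j in 1:tt) for (l in 1:k) {
    resid[i, j, l] <- y[i, j, l] - m_st[i, j] - m_sd[i, l] - m_td[j, l] +
      m_s[i] + m_t[j] + m_d[l] - gm
  }
  ss_tds <- sum(resid^2)

  f_of <- function(ss, df, ss_err, df_err) (ss / df) / (ss_err / df_err)
  tibble::tibble(
    effect = c("task", "distance", "task:distance"),
    df = c(tt - 1, k - 1, (tt - 1) * (k - 1)),
    df_error = c((tt - 1) * (n - 1), (k - 1) * (n - 1),
                 (tt - 1) * (k - 1) * (n - 1)),
    sumsq = c(ss_task, ss_dist, ss_td),
    sumsq_error = c(ss_task_subj, ss_dist_subj, ss_tds),
    statistic = c(
      f_of(ss_task, tt - 1, ss_task_subj, (tt - 1) * (n - 1)),
      f_of(ss_dist, k - 1, ss_dist_subj, (k - 1) * (n - 1)),
      f_of(ss_td, (tt - 1) * (k - 1), ss_tds, (tt - 1) * (k - 1) * (n - 1))),
    partial_eta_sq = c(ss_task / (ss_task + ss_task_subj),
                       ss_dist / (ss_dist + ss_dist_subj),
                       ss_td / (ss_td + ss_tds)),
    ss_subject = ss_subj)
}
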