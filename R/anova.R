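#' Task-by-Distance repeated-measures ANOVA on d' estimates
#'
#' Classical two-way within-subject analysis of variance on a complete
#' participants x tasks x distances grid of d' point estimates (one value
#' per participant per cell, typically posterior medians from the
#' categorical model; see [estimate_grid()]). Each effect is tested against
#' its own effect-by-subject interaction: `F = MS_effect / MS_(effect x
#' subject)`, with partial eta-squared `SS_effect / (SS_effect + SS_error)`.
#' For t tasks, k distances and n participants the degrees of freedom are
#' (t-1, (t-1)(n-1)) for Task, (k-1, (k-1)(n-1)) for Distance and
#' ((t-1)(k-1), (t-1)(k-1)(n-1)) for the interaction. No sphericity
#' correction is applied; the reported df are the uncorrected ones.
#'
#' The decomposition is delegated to [stats::aov()] with an
#' `Error(participant/(task*distance))` stratum specification.
#'
#' @param estimates Data frame with columns `participant_id`, `task`,
#'   `distance_m` (or `distance`), and `d_prime`: a complete crossing with
#'   at least 2 participants. Exclusions (e.g. an outlying participant) are
#'   plain row filters applied by the caller beforehand.
#' @return A tibble with one row per effect (`task`, `distance`,
#'   `task:distance`): `df`, `df_error`, `sumsq`, `sumsq_error`,
#'   `statistic` (F), `partial_eta_sq`, `p.value`.
#' @examples
#' grid <- tidyr::expand_grid(participant_id = paste0("P", 1:4),
#'                            task = c("detection", "localization"),
#'                            distance_m = c(1, 2, 3))
#' grid$d_prime <- stats::rnorm(nrow(grid), 2 - 0.4 * grid$distance_m)
#' rm_anova(grid)
#' @export
rm_anova <- function(estimates) {
  d <- tibble::as_tibble(estimates)
  if (!"distance_m" %in% names(d) && "distance" %in% names(d)) {
    d <- dplyr::rename(d, distance_m = "distance")
  }
  req <- c("participant_id", "task", "distance_m", "d_prime")
  if (!all(req %in% names(d))) {
    stop("`estimates` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(d[req])) stop("`estimates` contains missing values", call. = FALSE)

  n_part <- dplyr::n_distinct(d$participant_id)
  if (n_part < 2) stop("need at least 2 participants", call. = FALSE)
  counts <- dplyr::count(d, .data$participant_id, .data$task,
                         .data$distance_m)
  n_cells <- dplyr::n_distinct(d$task) * dplyr::n_distinct(d$distance_m)
  if (nrow(counts) != n_part * n_cells || any(counts$n != 1)) {
    stop("`estimates` must be a complete grid with exactly one d' per ",
         "participant, task and distance", call. = FALSE)
  }

  dat <- data.frame(
    y = d$d_prime,
    subject = factor(d$participant_id),
    task = factor(d$task),
    distance = factor(d$distance_m))

  total_ss <- sum((dat$y - mean(dat$y))^2)
  if (total_ss <= 1e-20) {
    stop("zero error variance: the d' estimates are constant, F is undefined",
         call. = FALSE)
  }
  eps <- 1e-12 * total_ss

  fit <- stats::aov(y ~ task * distance + Error(subject / (task * distance)),
                    data = dat)
  s <- summary(fit)

  pull_stratum <- function(effect, stratum_name) {
    tab <- s[[stratum_name]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    ie <- match("Residuals", rn)
    ss <- tab[i, "Sum Sq"]; ss_err <- tab[ie, "Sum Sq"]
    df <- tab[i, "Df"]; df_err <- tab[ie, "Df"]
    if (ss <= eps && ss_err <= eps) {
      # the effect is exactly absent (and so is its subject interaction):
      # report a null effect instead of a 0/0 ratio
      return(tibble::tibble(effect = effect, df = df, df_error = df_err,
                            sumsq = 0, sumsq_error = 0, statistic = 0,
                            partial_eta_sq = 0, p.value = 1))
    }
    if (!is.finite(ss_err) || ss_err <= eps) {
      stop("zero error variance for effect '", effect,
           "': F is undefined", call. = FALSE)
    }
    f <- (ss / df) / (ss_err / df_err)
    tibble::tibble(
      effect = effect, df = df, df_error = df_err,
      sumsq = ss, sumsq_error = ss_err,
      statistic = f,
      partial_eta_sq = ss / (ss + ss_err),
      p.value = stats::pf(f, df, df_err, lower.tail = FALSE))
  }

  dplyr::bind_rows(
    pull_stratum("task", "Error: subject:task"),
    pull_stratum("distance", "Error: subject:distance"),
    pull_stratum("task:distance", "Error: subject:task:distance"))
}
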