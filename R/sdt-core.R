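#' Sensitivity index d' from hit and false-alarm rates
#'
#' Closed-form equal-variance signal detection theory estimator
#' \eqn{d' = \Phi^{-1}(H) - \Phi^{-1}(F)}, where \eqn{H} is the proportion of
#' "signal" responses on signal-present trials and \eqn{F} the proportion on
#' signal-absent trials. \eqn{d' = 0} is chance; negative values are legal
#' (an observer systematically responding against the evidence) and are not
#' clamped.
#'
#' The estimator is undefined at boundary rates (0 or 1). Those raise an
#' error of class `echosdt_boundary_rate` rather than receiving a continuity
#' correction: the supported remedy for boundary cells is the Bayesian model
#' in [fit_sdt()], whose prior regularizes the estimate.
#'
#' @param hit_rate,false_alarm_rate Numeric vectors of proportions, strictly
#'   inside (0, 1). Recycled to a common length.
#' @return Numeric vector of sensitivity indices (unitless).
#' @seealso [criterion_from_rates()], [p_yes()], [fit_sdt()]
#' @examples
#' dprime_from_rates(0.8, 0.3)
#' dprime_from_rates(0.6915, 0.3085) # about 1: the 69%-correct unbiased observer
#' @export
dprime_from_rates <- function(hit_rate, false_alarm_rate) {
  check_rates(hit_rate, false_alarm_rate)
  stats::qnorm(hit_rate) - stats::qnorm(false_alarm_rate)
}

#' Response criterion c from hit and false-alarm rates
#'
#' Closed-form equal-variance SDT bias estimator
#' \eqn{c = -(\Phi^{-1}(H) + \Phi^{-1}(F))/2}. Negative \eqn{c} is a liberal
#' (yes-leaning) criterion, positive \eqn{c} a conservative one; an unbiased
#' observer has \eqn{c = 0}.
#'
#' @inheritParams dprime_from_rates
#' @return Numeric vector of criterion values (unitless).
#' @examples
#' criterion_from_rates(0.8, 0.3)
#' @export
criterion_from_rates <- function(hit_rate, false_alarm_rate) {
  check_rates(hit_rate, false_alarm_rate)
  -(stats::qnorm(hit_rate) + stats::qnorm(false_alarm_rate)) / 2
}

check_rates <- function(hit_rate, false_alarm_rate) {
  r <- c(hit_rate, false_alarm_rate)
  if (anyNA(r) || any(r < 0 | r > 1)) {
    stop("hit and false-alarm rates must be proportions in [0, 1]",
         call. = FALSE)
  }
  if (any(r == 0 | r == 1)) {
    stop(condition_boundary_rate())
  }
  invisible(NULL)
}

condition_boundary_rate <- function() {
  structure(
    class = c("echosdt_boundary_rate", "error", "condition"),
    list(message = paste0(
      "closed-form d'/c estimates are undefined when a hit or false-alarm ",
      "rate equals 0 or 1; fit the Bayesian model (fit_sdt) instead, which ",
      "regularizes boundary cells through its prior"),
      call = NULL)
  )
}

#' Trialwise probability of a "signal" response
#'
#' The Bernoulli observation model of the equal-variance SDT observer:
#' \deqn{p = (1-S)\,[1 - \Phi(c + d'/2)] + S\,[1 - \Phi(c - d'/2)]}
#' where \eqn{S} indicates whether the signal was present (1) or absent (0).
#' With \eqn{S = 1} this is the hit probability, with \eqn{S = 0} the
#' false-alarm probability. This is the likelihood kernel used by
#' [fit_sdt()] and the generative law used by [simulate_responses()].
#'
#' @param d_prime,criterion Finite numeric vectors of SDT parameters.
#' @param signal Indicator vector with values 0 or 1 (signal absent/present).
#' @return Vector of probabilities in \[0, 1\].
#' @examples
#' p_yes(1, 0, signal = 1) # hit probability of the unit-d' unbiased observer
#' p_yes(1, 0, signal = 0) # its false-alarm probability
#' @export
p_yes <- function(d_prime, criterion, signal) {
  if (!all(signal %in% c(0, 1))) {
    stop("`signal` must contain only 0 (absent) or 1 (present)", call. = FALSE)
  }
  if (anyNA(d_prime) || anyNA(criterion) ||
      any(!is.finite(d_prime)) || any(!is.finite(criterion))) {
    stop("`d_prime` and `criterion` must be finite", call. = FALSE)
  }
  (1 - signal) * (1 - stats::pnorm(criterion + d_prime / 2)) +
    signal * (1 - stats::pnorm(criterion - d_prime / 2))
}

#' Percent correct of an unbiased observer
#'
#' For an unbiased (\eqn{c = 0}) equal-variance observer, accuracy averaged
#' over signal-present and signal-absent trials is \eqn{100\,\Phi(d'/2)}.
#' \eqn{d' = 0} gives chance (50%) and \eqn{d' = 1} about 69% correct, the
#' conventional benchmark for above-chance echolocation performance.
#'
#' @param d_prime Finite numeric vector of sensitivity indices.
#' @return Percent correct, in (0, 100).
#' @examples
#' percent_correct_unbiased(c(0, 1, 2))
#' @export
percent_correct_unbiased <- function(d_prime) {
  if (anyNA(d_prime) || any(!is.finite(d_prime))) {
    stop("`d_prime` must be finite", call. = FALSE)
  }
  100 * stats::pnorm(d_prime / 2)
}

#' Add closed-form SDT estimates to a table of rates
#'
#' Convenience tidy wrapper: takes a data frame with hit-rate and
#' false-alarm-rate columns and appends `d_prime` and `criterion` columns
#' computed with [dprime_from_rates()] and [criterion_from_rates()].
#'
#' @param data A data frame.
#' @param hit_rate,false_alarm_rate Columns holding the rates (tidy-eval).
#' @return `data` as a tibble with `d_prime` and `criterion` appended.
#' @examples
#' tibble::tibble(h = c(0.8, 0.6), f = c(0.3, 0.4)) |>
#'   add_sdt_estimates(h, f)
#' @export
add_sdt_estimates <- function(data, hit_rate, false_alarm_rate) {
  dplyr::mutate(
    tibble::as_tibble(data),
    d_prime = dprime_from_rates({{ hit_rate }}, {{ false_alarm_rate }}),
    criterion = criterion_from_rates({{ hit_rate }}, {{ false_alarm_rate }})
  )
}
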