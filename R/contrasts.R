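#' Between-task sensitivity contrasts
#'
#' Draw-wise difference in sensitivity, detection d' minus localization d',
#' at each distance of a categorical fit, summarized by the posterior median
#' and an HPD interval. Positive values mean the participant detected
#' reflections better than they lateralized them. Computed from the draws,
#' never from the marginal summaries, so the interval accounts for the joint
#' posterior.
#'
#' @param fit A categorical `sdt_fit` covering both tasks.
#' @param mass HPD mass (defaults to the fit's).
#' @return A tibble: `participant_id`, `distance_m`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
task_contrasts <- function(fit, mass = fit$mass) {
  stopifnot(inherits(fit, "sdt_fit"))
  if (fit$model != "categorical") {
    stop("task_contrasts() needs a categorical fit (got ", fit$model, ")",
         call. = FALSE)
  }
  distances <- sort(unique(fit$summary$distance_m))
  purrr::map_dfr(distances, function(x) {
    det <- sprintf("dprime[detection,%.2f]", x)
    loc <- sprintf("dprime[localization,%.2f]", x)
    if (!all(c(det, loc) %in% colnames(fit$draws))) {
      stop("both tasks are needed at every distance; missing at ",
           sprintf("%.2f m", x), call. = FALSE)
    }
    diff <- fit$draws[, det] - fit$draws[, loc]
    hpd <- hpd_interval(diff, mass)
    tibble::tibble(participant_id = fit$participant_id, distance_m = x,
                   estimate = stats::median(diff),
                   conf.low = hpd[["lower"]], conf.high = hpd[["upper"]])
  })
}

#' Response-bias comparison table
#'
#' Summarizes the response-bias parameter c for one participant under both
#' models, mirroring the conventional report layout. From the categorical
#' fit: the draw-wise mean of the per-distance criteria per task and the
#' draw-wise between-task difference of those means, with an HPD interval.
#' From the exponential fit: the two distance-constant criteria and their
#' difference. Negative c is a yes-leaning (liberal) criterion.
#'
#' Full precision is retained; round for presentation (reports conventionally
#' print one decimal).
#'
#' @param fit_categorical,fit_exponential `sdt_fit` objects for the same
#'   participant.
#' @param mass HPD mass.
#' @return A one-row tibble with columns `participant_id`,
#'   `m1_c_detection`, `m1_c_localization`, `m1_difference`, `m1_conf.low`,
#'   `m1_conf.high`, `m2_c_detection`, `m2_c_localization`, `m2_difference`,
#'   `m2_conf.low`, `m2_conf.high`.
#' @export
bias_table <- function(fit_categorical, fit_exponential, mass = 0.95) {
  stopifnot(inherits(fit_categorical, "sdt_fit"),
            inherits(fit_exponential, "sdt_fit"))
  if (fit_categorical$model != "categorical" ||
      fit_exponential$model != "exponential") {
    stop("bias_table() takes a categorical fit then an exponential fit",
         call. = FALSE)
  }
  if (!identical(fit_categorical$participant_id,
                 fit_exponential$participant_id)) {
    stop("fits are for different participants (",
         fit_categorical$participant_id, " vs ",
         fit_exponential$participant_id, ")", call. = FALSE)
  }

  cat_terms <- fit_categorical$summary
  mean_c_draws <- function(tk) {
    cols <- cat_terms$term[cat_terms$parameter == "criterion" &
                             cat_terms$task == tk]
    rowMeans(fit_categorical$draws[, cols, drop = FALSE])
  }
  m1_det <- mean_c_draws("detection")
  m1_loc <- mean_c_draws("localization")
  m1_diff <- m1_det - m1_loc
  m1_hpd <- hpd_interval(m1_diff, mass)

  m2_det <- fit_exponential$draws[, "c0"]
  m2_loc <- fit_exponential$draws[, "c1"]
  m2_diff <- m2_det - m2_loc
  m2_hpd <- hpd_interval(m2_diff, mass)

  tibble::tibble(
    participant_id = fit_categorical$participant_id,
    m1_c_detection = stats::median(m1_det),
    m1_c_localization = stats::median(m1_loc),
    m1_difference = stats::median(m1_diff),
    m1_conf.low = m1_hpd[["lower"]], m1_conf.high = m1_hpd[["upper"]],
    m2_c_detection = stats::median(m2_det),
    m2_c_localization = stats::median(m2_loc),
    m2_difference = stats::median(m2_diff),
    m2_conf.low = m2_hpd[["lower"]], m2_conf.high = m2_hpd[["upper"]])
}

#' Collect d' point estimates across participants
#'
#' Builds the participants x tasks x distances grid of posterior-median d'
#' estimates that the group-level ANOVA consumes, from a list of fits as
#' returned by [fit_participants()] (categorical fits are used).
#'
#' @param fits A list of `sdt_fit` objects, or the nested list returned by
#'   [fit_participants()].
#' @return Tibble with `participant_id`, `task`, `distance_m`, `d_prime`.
#' @export
estimate_grid <- function(fits) {
  flat <- purrr::list_flatten(purrr::map(fits, function(f) {
    if (inherits(f, "sdt_fit")) list(f) else f
  }))
  cats <- purrr::keep(flat, ~ inherits(.x, "sdt_fit") &&
                        .x$model == "categorical")
  if (!length(cats)) stop("no categorical fits supplied", call. = FALSE)
  purrr::map_dfr(cats, function(f) {
    dplyr::transmute(
      dplyr::filter(f$summary, .data$parameter == "d_prime"),
      participant_id = f$participant_id,
      task = .data$task, distance_m = .data$distance_m,
      d_prime = .data$estimate)
  })
}
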