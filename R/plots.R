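#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SDT fit
#'
#' Sensitivity d' against reflector distance by task. Categorical fits are
#' drawn as points with HPD error bars; exponential fits as the posterior-
#' median curve with an HPD ribbon.
#'
#' @param object An `sdt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdt_fit
#' @export
autoplot.sdt_fit <- function(object, ...) {
  pred <- predict_dprime(object)
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$distance_m,
                                          y = .data$estimate,
                                          colour = .data$task)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "distance to reflector (m)", y = "sensitivity d'",
      colour = NULL, fill = NULL,
      title = sprintf("participant %s (%s model)", object$participant_id,
                      object$model),
      subtitle = sprintf("medians with %.0f%% HPD intervals",
                         100 * object$mass)) +
    ggplot2::theme_minimal()
  if (object$model == "categorical") {
    p + ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                              ymax = .data$conf.high),
                                 position = ggplot2::position_dodge(0.08))
  } else {
    p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high,
                                          fill = .data$task),
                             alpha = 0.2, colour = NA) +
      ggplot2::geom_line()
  }
}

#' Plot between-task d' contrasts
#'
#' @param contrasts A tibble from [task_contrasts()].
#' @return A ggplot object.
#' @export
plot_task_contrasts <- function(contrasts) {
  ggplot2::ggplot(contrasts, ggplot2::aes(x = .data$distance_m,
                                          y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = "distance to reflector (m)",
                  y = "detection d' - localization d'") +
    ggplot2::theme_minimal()
}
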