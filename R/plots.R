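# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.stress_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Class",
                  title = "One-vs-rest ROC",
                  subtitle = paste(sprintf("%s: AUC = %.2f",
                                           names(object$auc), object$auc),
                                   collapse = "   ")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stress_confusion <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$truth,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted", y = "True", fill = "Count",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vr_session <- function(object, ...) {
  motion <- dplyr::mutate(object$motion,
                          speed = motion_speed(object$motion))
  traces <- dplyr::bind_rows(
    tibble::tibble(t = motion$t, value = motion$speed,
                   trace = "controller speed (units/s)"),
    if (!is.null(object$gsr)) {
      tibble::tibble(t = object$gsr$t, value = object$gsr$conductance_uS,
                     trace = "GSR (uS)")
    }
  )
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = paste0("Session ", object$id,
                                 " (", object$condition, ")")) +
    ggplot2::theme_minimal()
  if (nrow(object$stressors) > 0) {
    p <- p + ggplot2::geom_vline(data = object$stressors,
                                 ggplot2::aes(xintercept = .data$t_onset),
                                 colour = "red", alpha = 0.4,
                                 linetype = "dotted")
  }
  p
}

#' Plot a decision trace
#'
#' Fused score Sf over time with alert ticks, from [detect_session()]
#' output.
#'
#' @param decisions A decisions tibble.
#' @return A ggplot object.
#' @export
plot_decisions <- function(decisions) {
  ggplot2::ggplot(decisions, ggplot2::aes(x = .data$t, y = .data$Sf)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_point(data = dplyr::filter(decisions, .data$alert),
                        ggplot2::aes(colour = factor(.data$tier)), size = 1) +
    ggplot2::labs(x = "Time (s)", y = expression(S[f]), colour = "Alert tier",
                  title = "Stress decisions") +
    ggplot2::theme_minimal()
}

#' Boxplots of the three stress features by class
#'
#' @param features A feature tibble (`class, hesitation_s, tremble_units,
#'   gsr_uS`).
#' @return A ggplot object.
#' @export
plot_class_features <- function(features) {
  long <- tidyr::pivot_longer(features,
                              cols = c("hesitation_s", "tremble_units", "gsr_uS"),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Stress features by class") +
    ggplot2::theme_minimal()
}
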