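#' Plot a ROC curve
#'
#' @param object A `mohi_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mohi_roc
#' @export
autoplot.mohi_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve, AUC = %.2f (%d%% CI %.2f-%.2f)",
                      object$auc, round(100 * object$conf_level),
                      object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Plot group means with confidence intervals
#'
#' Group means of the compared score with their confidence intervals;
#' homogeneous-subset letters are printed above the points when present.
#'
#' @param object A `mohi_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mohi_comparison
#' @export
autoplot.mohi_comparison <- function(object, ...) {
  g <- object$groups
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::labs(x = object$variable, y = "Mean score",
                  subtitle = sprintf("%s, p = %.3g", object$method, object$p_value)) +
    ggplot2::theme_minimal()
  if ("subset" %in% names(g)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(y = .data$ci_high, label = .data$subset),
                                vjust = -0.8)
  }
  p
}

#' Histogram of the MOHi distribution
#'
#' The cohort MOHi distribution on its 0-3 scale, with the degraded-oral-
#' health cutoff (1.5) marked.
#'
#' @param data A scored cohort with a `mohi` column.
#' @param binwidth Histogram bin width on the MOHi scale.
#' @return A ggplot.
#' @export
plot_mohi_distribution <- function(data, binwidth = 0.1) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$mohi)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = MOHI_DEGRADED_CUTOFF, linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(0, 3)) +
    ggplot2::labs(x = "MOHi (0 = best, 3 = most degraded)", y = "Participants") +
    ggplot2::theme_minimal()
}
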