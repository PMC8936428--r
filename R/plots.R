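# Diagnostic ggplot2 figures for the main result types.

#' Variance-explained curve of a PLS fit
#'
#' Cumulative fraction of response variance against component count, with
#' the selection threshold drawn as a reference line.
#'
#' @param object A [pls1_fit()] object.
#' @param threshold Reference threshold (default 0.9); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls1_fit <- function(object, threshold = 0.9, ...) {
  df <- tibble(component = seq_len(object$ncomp),
               cum_var = object$cum_var)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$cum_var)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "PLS components",
                  y = "Cumulative variance explained in gains")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' VIP score bar chart
#'
#' @param vip Tibble from [vip_scores()].
#' @param threshold Selection cut-off drawn as a reference line (default 1).
#' @return A ggplot object.
#' @export
plot_vip <- function(vip, threshold = 1.0) {
  vip <- vip %>% mutate(selected = .data$vip >= threshold)
  ggplot2::ggplot(
    vip,
    ggplot2::aes(stats::reorder(.data$predictor, -.data$vip), .data$vip,
                 fill = .data$selected)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "VIP score", fill = "Selected") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Predicted-versus-observed gains
#'
#' @param object An [evaluate_predictions()] report.
#' @param ... Unused.
#' @return A ggplot object with the identity line and the correlation in the
#'   subtitle.
#' @export
autoplot.prediction_report <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(.data$observed_delta,
                               .data$predicted_delta)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Observed gain (FMA-UE points)",
      y = "Predicted gain (FMA-UE points)",
      subtitle = sprintf("r = %.2f, RMSE = %.2f", object$r_delta,
                         object$rmse)
    )
}

#' Network coherence by recovery group
#'
#' Box plots of the five network coherences per band, split by recovery
#' label.
#'
#' @param network_values Tibble from [network_aggregate()].
#' @param labels Tibble with `subject_id` and `recovery`.
#' @return A ggplot object faceted by band.
#' @export
plot_network_comparison <- function(network_values, labels) {
  dat <- left_join(network_values,
                   labels %>% select("subject_id", "recovery"),
                   by = "subject_id")
  ggplot2::ggplot(dat, ggplot2::aes(.data$network, .data$value,
                                    fill = .data$recovery)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = NULL, y = "Coherence", fill = "Recovery") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
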