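# ggplot2 views of the package's result types.

#' Plot cluster failure-probability curves
#'
#' @param curves Long tibble from [reliability_curves()].
#' @return A ggplot: PF(I) against gamma on log-log axes, one line per node
#'   count.
#' @export
plot_reliability_curves <- function(curves = reliability_curves()) {
  ggplot2::ggplot(
    dplyr::filter(curves, .data$pf > 0),
    ggplot2::aes(.data$gamma, .data$pf, colour = factor(.data$I))
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(gamma == "mean repair / mean lifetime"),
      y = "cluster failure probability",
      colour = "nodes"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a broker delay profile
#'
#' @param profile Tibble from [delay_profile()].
#' @return A ggplot of mean sojourn time against cluster size with 1-SE
#'   error bars.
#' @export
plot_delay_profile <- function(profile) {
  ggplot2::ggplot(
    profile,
    ggplot2::aes(.data$n_nodes, .data$mean_delay)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_delay - .data$se,
      ymax = .data$mean_delay + .data$se
    )) +
    ggplot2::labs(
      x = "broker nodes", y = "mean sojourn time",
      title = "Load balancing: delay against cluster size"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn train_ensemble Bar chart of validation metrics per member and
#'   for the fused rule.
#' @param object An `ards_ensemble` (for `autoplot`).
#' @method autoplot ards_ensemble
#' @export
autoplot.ards_ensemble <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("auc", "f1", "precision", "accuracy")),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$member, .data$value, fill = .data$metric)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "validation metric") +
    ggplot2::theme_minimal()
}
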