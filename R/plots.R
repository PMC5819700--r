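#' Plot zone efficiency trajectories
#'
#' Mean efficiency per zone over time, one panel per measure, from the
#' output of [aggregate_by_zone()] (or the `zone_efficiency` element of a
#' pipeline run).
#'
#' @param zone_summary tibble with `zone`, a period column, `measure`,
#'   `mean`.
#' @param period name of the period column.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(zone_summary, period = "year") {
  stopifnot(all(c("zone", period, "measure", "mean") %in%
                  names(zone_summary)))
  ggplot2::ggplot(zone_summary,
                  ggplot2::aes(x = .data[[period]], y = .data$mean,
                               colour = .data$zone,
                               group = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean efficiency", colour = "zone") +
    ggplot2::theme_minimal()
}

#' Plot Malmquist decomposition factors
#'
#' Per-unit Malmquist index and decomposition factors across adjacent
#' period pairs, with the no-change level 1 marked.
#'
#' @param malmquist_records output of [malmquist()].
#' @return A ggplot object.
#' @export
plot_malmquist <- function(malmquist_records) {
  long <- malmquist_records |>
    tidyr::pivot_longer(dplyr::all_of(c("mi", "tc", "ec", "ptec", "sec")),
                        names_to = "factor", values_to = "value") |>
    dplyr::mutate(pair = paste(.data$period_from, .data$period_to,
                               sep = "-"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = "period pair", y = "factor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Coefficient plot for a Cobb-Douglas panel fit
#'
#' @param object a `cd_panel_fit`.
#' @param ... unused.
#' @return A ggplot object (dot-and-interval plot of the coefficients
#'   with approximate 95% intervals).
#' @export
autoplot.cd_panel_fit <- function(object, ...) {
  co <- tidy(object)
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = paste(object$effect, "form")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
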