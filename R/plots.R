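# ggplot2 views of the result objects. Plots are side-products for
# inspection; all tested quantities live in the tabular results.

#' @describeIn grid_search Heatmap of the objective surface over
#'   gamma x beta, faceted by decay family, with the selected optimum
#'   marked.
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @method autoplot calibration_result
#' @export
autoplot.calibration_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  obj <- attr(object, "objective")
  best <- dplyr::filter(df, .data$best)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beta, y = .data$gamma,
    fill = .data[[obj]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = best, shape = 4, size = 3, colour = "white") +
    ggplot2::facet_wrap(~family) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "distance decay (beta)", y = "population scaling (gamma)",
      fill = obj,
      title = "Calibration surface (x marks the selected optimum)"
    )
}

#' @describeIn tri_migration_stats Box-style plot (5th-95th percentile
#'   whiskers, quartile boxes, median bar) of net migration per TRI group
#'   and interval.
#' @param object A `group_box_stats` tibble.
#' @param ... Unused.
#' @method autoplot group_box_stats
#' @export
autoplot.group_box_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$tri_group))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p5, ymax = .data$p95), width = 0.25) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      fill = "grey85", width = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 18, colour = "firebrick") +
    ggplot2::facet_wrap(~interval) +
    ggplot2::labs(
      x = "TRI quantile group (5 = most rugged)",
      y = "net migration",
      title = "Net migration by terrain ruggedness group"
    )
}

#' Scatter of network against Euclidean pair distances
#'
#' Every point is an origin-destination pair; the dashed line is the
#' identity, below which no point should fall when road edges are at least
#' as long as their straight-line chords.
#'
#' @param elongation Result of [elongation_summary()].
#' @return A ggplot.
#' @export
plot_elongation <- function(elongation) {
  ggplot2::ggplot(elongation$pairs, ggplot2::aes(.data$euclid_km, .data$network_km)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Euclidean distance (km)", y = "network distance (km)",
      title = "Network vs straight-line separation"
    )
}

#' Map of a thresholded flow network
#'
#' Draws retained flows as segments between settlement coordinates, scaled
#' by flow volume, with nodes sized by inflow.
#'
#' @param network A `flow_network` with coordinates on its nodes.
#' @return A ggplot.
#' @export
plot_flow_network <- function(network) {
  if (!all(c("x", "y") %in% names(network$nodes))) {
    abort_field("network", "nodes carry no coordinates; pass settlements to export_flow_network()")
  }
  seg <- network$edges |>
    dplyr::left_join(network$nodes[c("id", "x", "y")], by = c(origin = "id")) |>
    dplyr::left_join(network$nodes[c("id", "x", "y")],
      by = c(destination = "id"), suffix = c("", "_to")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
        linewidth = .data$flow
      ),
      alpha = 0.35, colour = "steelblue"
    ) +
    ggplot2::geom_point(
      data = network$nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$inflow),
      colour = "grey25"
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 2)) +
    ggplot2::scale_size(range = c(0.3, 4)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (km)", y = "y (km)",
      title = sprintf("Migration flows above %g migrants", network$threshold)
    )
}

#' Histogram panel of migration-flow distributions
#'
#' @param distributions Result of [flow_distributions()].
#' @param scale `"log10"` or `"linear"` bins.
#' @return A ggplot faceted by interval and measure.
#' @export
plot_flow_distributions <- function(distributions, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  df <- if (scale == "log10") distributions$log_bins else distributions$linear_bins
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$count
  )) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::facet_grid(interval ~ measure, scales = "free") +
    (if (scale == "log10") ggplot2::scale_x_log10() else ggplot2::scale_x_continuous()) +
    ggplot2::labs(x = "settlement-level volume", y = "settlements")
}
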