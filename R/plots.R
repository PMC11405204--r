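#' Spike raster plot
#'
#' @param trains A `spike_trains` object.
#' @return A ggplot.
#' @export
plot_raster <- function(trains) {
  stopifnot(inherits(trains, "spike_trains"))
  ggplot2::ggplot(trains, ggplot2::aes(x = .data$time_s,
                                       y = .data$electrode)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::labs(x = "time (s)", y = "electrode") +
    ggplot2::theme_minimal()
}

#' @describeIn pairwise_fc Heatmap of the Fisher-z connectivity matrix.
#' @param object An `fc_matrix`.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "electrode i", y = "electrode j",
                  fill = "Fisher z") +
    ggplot2::theme_minimal()
}

#' @describeIn pca_embed Two-component trajectory plot with day labels.
#' @param object A `well_trajectory`.
#' @param ... Unused.
#' @export
autoplot.well_trajectory <- function(object, ...) {
  if (is.null(object$pc_coords)) abort("run pca_embed() first")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_path(color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = paste("Day", .data$day)),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' @describeIn threshold_network Grid plot of thresholded connections;
#'   warmer/thicker edges are stronger, node size tracks degree.
#' @param object A `network_graph`.
#' @param ... Unused.
#' @export
autoplot.network_graph <- function(object, ...) {
  n <- nrow(object$degrees)
  side <- ceiling(sqrt(n))
  pos <- tibble(electrode = seq_len(n),
                x = (seq_len(n) - 1L) %% side,
                y = (seq_len(n) - 1L) %/% side)
  edges <- object$edges %>%
    dplyr::left_join(pos, by = c(i = "electrode")) %>%
    dplyr::left_join(pos, by = c(j = "electrode"),
                     suffix = c("", "_end"))
  nodes <- dplyr::left_join(pos, object$degrees, by = "electrode")
  p <- ggplot2::ggplot()
  if (nrow(edges))
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, color = .data$z,
                   linewidth = .data$z)) +
      ggplot2::scale_color_gradient(low = "yellow", high = "red") +
      ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none")
  p + ggplot2::geom_point(data = nodes,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       size = .data$degree),
                          color = "steelblue") +
    ggplot2::scale_size(range = c(1, 5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "Fisher z", size = "degree") +
    ggplot2::theme_void()
}

#' Normalized firing-rate course by group
#'
#' @param mfr_tbl Tibble with columns `well`, `group`, `day`, `norm_mfr`
#'   (as returned in `run_mea_pipeline()$mfr`).
#' @return A ggplot.
#' @export
plot_mfr_course <- function(mfr_tbl) {
  ggplot2::ggplot(mfr_tbl,
                  ggplot2::aes(x = .data$day, y = .data$norm_mfr,
                               color = .data$group,
                               group = .data$well)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(ggplot2::aes(group = .data$group),
                          fun = mean, geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "day", y = "MFR / Day-0 MFR") +
    ggplot2::theme_minimal()
}
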