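#' Plot per-well kinetic curves
#'
#' One line per well of the chosen metric over time; when a layout is
#' supplied, lines are coloured by treatment.
#'
#' @param timeseries Time-series tibble from [build_timeseries()] (or the
#'   `timeseries` element of a `phago_run`).
#' @param metric Metric to plot (default `"object_count"`).
#' @param layout Optional layout tibble for treatment colouring.
#' @return A ggplot object.
#' @export
plot_timeseries <- function(timeseries, metric = "object_count",
                            layout = NULL) {
  df <- dplyr::filter(timeseries, .data$metric == !!metric)
  if (!is.null(layout))
    df <- dplyr::left_join(df, layout, by = "well_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_min, y = .data$value, group = .data$well_id))
  p <- if (!is.null(layout))
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$treatment)) else
    p + ggplot2::geom_line()
  p + ggplot2::labs(x = "time (min)", y = metric) + ggplot2::theme_minimal()
}

#' @rdname plot_timeseries
#' @param object A `phago_run` from [analyze_plate()].
#' @param ... Passed to [plot_timeseries()].
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.phago_run <- function(object, ...) {
  plot_timeseries(object$timeseries, layout = object$layout, ...)
}

#' Plot an object mask over a corrected frame
#'
#' QC view of one segmented frame: corrected intensity as a raster with
#' detected object outlines (bounding boxes) overlaid.
#'
#' @param corrected Corrected intensity matrix.
#' @param objects Object tibble from [measure_objects()].
#' @return A ggplot object.
#' @export
plot_objects <- function(corrected, objects) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(corrected)) - 1L, times = ncol(corrected)),
    col = rep(seq_len(ncol(corrected)) - 1L, each = nrow(corrected)),
    intensity = as.vector(corrected))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "green") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(objects) > 0)
    p <- p + ggplot2::geom_rect(
      data = objects,
      ggplot2::aes(xmin = .data$bbox_c0 - 0.5, xmax = .data$bbox_c1 - 0.5,
                   ymin = .data$bbox_r0 - 0.5, ymax = .data$bbox_r1 - 0.5),
      inherit.aes = FALSE, colour = "magenta", fill = NA, linewidth = 0.3)
  p
}
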