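# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the posture map
#'
#' Embedded points colored by posture over the density basins.
#'
#' @param object a `posture_map` from [watershed_postures()].
#' @param max_points subsample cap for drawing.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.posture_map <- function(object, max_points = 20000, ...) {
  pts <- tibble::tibble(dim1 = object$points[, 1], dim2 = object$points[, 2],
                        posture = factor(object$labels))
  if (nrow(pts) > max_points)
    pts <- pts[seq(1, nrow(pts), length.out = max_points), ]
  ggplot2::ggplot(pts, ggplot2::aes(.data$dim1, .data$dim2,
                                    color = .data$posture)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = "embedding dim 1", y = "embedding dim 2",
                  title = sprintf("%d postures", object$n_postures)) +
    ggplot2::theme_minimal()
}

#' Plot a metric-versus-lag curve, optionally with its exponential fit
#'
#' @param object a `metric_curve` (or `timescale_fit`).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.metric_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "transition lag (runs)",
                  y = attr(object, "metric") %||% "value") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.metric_curve
#' @export
autoplot.timescale_fit <- function(object, ...) {
  df <- object$curve
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::labs(x = "transition lag (runs)", y = "metric",
                  subtitle = if (is.na(object$half_life)) "degenerate fit"
                  else sprintf("half-life %.1f lags", object$half_life)) +
    ggplot2::theme_minimal()
}

#' Plot a shuffle-null distribution against the observed value
#'
#' @param object a `null_distribution` from [shuffle_null()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy.null_distribution(object), ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(x = object$metric,
                  subtitle = sprintf("p = %.4g (%d shuffles)",
                                     object$p_value, object$n)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a transition probability matrix
#'
#' @param object a `transition_graph`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.transition_graph <- function(object, ...) {
  df <- tidy.transition_graph(object)
  df$from <- factor(df$from, levels = object$postures)
  df$to <- factor(df$to, levels = object$postures)
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "from posture", y = "to posture",
                  title = sprintf("lag %d", object$lag)) +
    ggplot2::theme_minimal()
}

#' Dendrogram plot of the behavioral hierarchy
#'
#' @param x a `behavioral_dendrogram`.
#' @param ... passed to [plot.hclust()].
#' @export
plot.behavioral_dendrogram <- function(x, ...) {
  plot(as.hclust.behavioral_dendrogram(x), ...)
}
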