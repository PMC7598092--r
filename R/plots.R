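#' Plot population activity across snapshots
#'
#' Mean (line) and per-region (points) activity of each population at every
#' snapshot time.
#'
#' @param object A [snapshot_series()] or `brainmass_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snapshot_series
#' @export
autoplot.snapshot_series <- function(object, ...) {
  df <- tidy(object, what = "activity")
  means <- dplyr::summarise(dplyr::group_by(df, .data$time, .data$variable),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 1000, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_line(data = means, linewidth = 0.8) +
    ggplot2::labs(x = "biological time [s]", y = "population activity",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.snapshot_series
#' @method autoplot brainmass_sim
#' @export
autoplot.brainmass_sim <- function(object, ...) {
  series <- object$series %||% read_series(object$out_dir)
  autoplot(series, ...)
}

#' Heatmap of the inter-region weight matrix at a snapshot
#'
#' @param x A [snapshot_series()] or `brainmass_sim`.
#' @param time Snapshot time (ms); defaults to the last snapshot.
#' @return A ggplot object.
#' @export
plot_weight_matrix <- function(x, time = NULL) {
  series <- if (inherits(x, "brainmass_sim")) x$series %||% read_series(x$out_dir) else x
  stopifnot(inherits(series, "snapshot_series"), length(series$times) > 0)
  if (is.null(time)) time <- max(series$times)
  k <- which(series$times == time)
  if (length(k) != 1) abort("plot_weight_matrix: no snapshot at that time.")
  W <- series$W[[k]]
  df <- tibble(to = as.integer(row(W)), from = as.integer(col(W)),
               weight = as.vector(W))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("inter-region weights at t = %g s", time / 1000),
                  x = "source region", y = "target region") +
    ggplot2::theme_minimal()
}

#' Log-log plot of coupling work versus network size
#'
#' @param object A `brainmass_bench` tibble from [benchmark_scaling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brainmass_bench
#' @export
autoplot.brainmass_bench <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$coupling_madds)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "regions (log)", y = "coupling multiply-adds (log)") +
    ggplot2::theme_minimal()
}
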