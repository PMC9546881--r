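## ggplot2 displays for scenes and benchmark reports.

#' Plot one simulated frame
#'
#' Renders a frame as a gray raster with the ground-truth head positions
#' overlaid, colored by swim mode.
#'
#' @param scene A `casa_scene` from [simulate_semen()].
#' @param frame 0-based frame index.
#' @param truth Overlay ground truth? (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_frame <- function(scene, frame = 0, truth = TRUE) {
  stopifnot(inherits(scene, "casa_scene"))
  f <- scene$frames[[frame + 1L]]
  df <- tidyr::expand_grid(y = seq_len(nrow(f)) - 1L,
                           x = seq_len(ncol(f)) - 1L)
  df$gray <- as.vector(t(f))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
  if (truth) {
    tr <- dplyr::filter(scene$truth, .data$frame == !!frame)
    if (nrow(tr) > 0) {
      p <- p + ggplot2::geom_point(
        data = tr, ggplot2::aes(.data$x, .data$y, color = .data$mode),
        shape = 1, size = 4)
    }
  }
  p
}

#' Plot a detection noise sweep
#'
#' Replicate-mean OSPA, precision and recall per algorithm against the
#' noise variance, one panel per metric.
#'
#' @param object A `casa_sweep` from [detection_noise_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.casa_sweep <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("ospa", "precision", "recall"),
                        names_to = "metric") |>
    dplyr::group_by(.data$algorithm, .data$noise_var, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$noise_var, .data$value,
                                     color = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "noise variance (gray^2)", y = NULL,
                  color = "algorithm") +
    ggplot2::theme_minimal()
}

#' Plot a tracking benchmark
#'
#' Replicate-mean MOTA (and the component rates) per tracker against the
#' number of cells.
#'
#' @param object A `casa_benchmark` from [tracking_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.casa_benchmark <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("motp", "fp", "miss", "mme", "mota"),
                        names_to = "metric") |>
    dplyr::group_by(.data$tracker, .data$n_cells, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$n_cells, .data$value,
                                     color = .data$tracker)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of cells", y = NULL, color = "tracker") +
    ggplot2::theme_minimal()
}
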