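# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an Rxy delay curve
#'
#' Mean Rxy against delay, with the significance cutoff and the 0-1 min
#' readout window marked.
#'
#' @param object an `rxy_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rxy_curve <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.4
  win <- attr(object, "window_s") %||% 60
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delay_s, y = .data$rxy)) +
    ggplot2::annotate("rect", xmin = 0, xmax = win, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "delay (s, switch after reversal)",
                  y = "Rxy", title = sprintf(
                    "Cross-correlation of switching and reversals (n = %s)",
                    attr(object, "n_cells") %||% "?")) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-occurrence histogram
#'
#' Occurrence of fluorescent clusters per axial segment (pole to pole).
#'
#' @param object a `localization_histogram`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.localization_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$segment),
                                       y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cell position (15 equal segments, pole to pole)",
                  y = "fraction of cells with a cluster",
                  title = sprintf("Cluster occurrence (n = %d cells)",
                                  attr(object, "n_cells"))) +
    ggplot2::theme_minimal()
}

#' Plot pole-intensity time series
#'
#' Fluorescence at the initial leading and initial lagging pole over time.
#'
#' @param object a `pole_series`.
#' @param frame_interval seconds per frame.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pole_series <- function(object, frame_interval = 30, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("initial_leading_au", "initial_lagging_au"),
                              names_to = "pole", values_to = "intensity_au")
  long$pole <- sub("_au$", "", long$pole)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame * frame_interval / 60,
                                     y = .data$intensity_au,
                                     colour = .data$pole)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(initial_leading = "#2166ac",
                                            initial_lagging = "#b2182b")) +
    ggplot2::labs(x = "time (min)", y = "pole intensity (au)") +
    ggplot2::theme_minimal()
}

#' Plot tracks
#'
#' Centroid trajectories coloured by track.
#'
#' @param tracks tibble from [link_tracks()].
#' @return a ggplot.
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(tracks, ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$track_id,
                                       colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
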