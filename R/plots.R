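#' Plot a gait signal
#' @param object A `gait_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$angle_deg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "knee flexion (deg)",
                  title = attr(object, "subject_id"))
}

#' Plot IMFs and residual as stacked facets
#' @param object A `gait_imf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_imf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a Hilbert spectrum as a time-frequency raster
#' @param object A `hilbert_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hilbert_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$time_s, .data$freq_hz, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$mode) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' Plot an energy trace, optionally with detected turn segments shaded
#' @param object An `energy_trace`.
#' @param segments Optional `gait_segments` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_trace <- function(object, segments = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$energy)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "Hilbert energy")
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(segments),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2, fill = "firebrick"
    )
  }
  p
}
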