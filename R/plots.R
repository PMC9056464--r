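#' Plot windowed respiratory-rate estimates
#'
#' Estimated rate per window over time, with skipped windows marked at
#' the axis and the reference series overlaid when available.
#'
#' @param object A `respyre_estimates` tibble from [estimate_record()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot respyre_estimates
#' @export
autoplot.respyre_estimates <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid_s <- df$start_s + df$window_s / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_s, y = .data$respr)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linetype = "dotted", na.rm = TRUE)
  ref <- attr(object, "ref_resp")
  if (!is.null(ref) && nrow(ref) > 0) {
    p <- p + ggplot2::geom_line(
      data = ref,
      ggplot2::aes(x = .data$time_s, y = .data$resp_brpm),
      colour = "grey50", inherit.aes = FALSE
    )
  }
  if (any(df$skipped)) {
    p <- p + ggplot2::geom_rug(
      data = df[df$skipped, ], ggplot2::aes(x = .data$mid_s),
      sides = "b", colour = "red", inherit.aes = FALSE
    )
  }
  p +
    ggplot2::labs(x = "time (s)", y = "respiratory rate (breaths/min)") +
    ggplot2::theme_minimal()
}

#' Plot a power spectral density with the respiratory band highlighted
#'
#' @param object A `spectral_estimate` from [welch_psd()].
#' @param band_low_hz,band_high_hz Band to shade (defaults 0.1-0.4 Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_estimate
#' @export
autoplot.spectral_estimate <- function(object, band_low_hz = 0.1,
                                       band_high_hz = 0.4, ...) {
  df <- tidy.spectral_estimate(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$psd)) +
    ggplot2::annotate("rect", xmin = band_low_hz, xmax = band_high_hz,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, min(1, max(df$freq_hz)))) +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (ms²/Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a window-size sweep
#'
#' MAE and RMSE per candidate window size, as produced by
#' [sweep_windows()].
#'
#' @param sweep Tibble from [sweep_windows()].
#' @return A ggplot object.
#' @export
plot_window_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep[, c("window_s", "mae", "rmse")],
                              c("mae", "rmse"),
                              names_to = "metric", values_to = "error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_s, y = .data$error,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window size (s)", y = "error (breaths/min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
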