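#' @importFrom ggplot2 autoplot
NULL

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param db Plot power in dB (`10 * log10`)? Default FALSE.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.power_spectrum <- function(object, db = FALSE, ...) {
  df <- tibble::tibble(freq_hz = object$freq_hz,
                       power = if (db) 10 * log10(pmax(object$power, .Machine$double.xmin))
                               else object$power)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency [Hz]",
                  y = if (db) "PSD [dB]" else "PSD [units²/Hz]",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a centre-of-mass motion trace
#'
#' @param object A `motion_trace`.
#' @param ... Ignored.
#' @return A ggplot with the two centred coordinate series over time.
#' @exportS3Method ggplot2::autoplot
autoplot.motion_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(tibble::as_tibble(object), .data$time_s,
                     xc = .data$xc - mean(.data$xc), yc = .data$yc - mean(.data$yc)),
    c("xc", "yc"), names_to = "coordinate", values_to = "displacement")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$displacement,
                                   colour = .data$coordinate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time [s]", y = "Centred CoM displacement [px]",
                  title = attr(object, "roi_label")) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A `bland_altman` result.
#' @param ... Ignored.
#' @return A ggplot: per-subject points at (mean, difference), a solid mean
#'   line and dashed 95% limits of agreement.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$avg, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of modalities", y = "Video - IMU") +
    ggplot2::theme_minimal()
}

#' Correlation panel for paired metrics
#'
#' Scatter of video- against IMU-derived values with a least-squares fit
#' line and the identity line.
#'
#' @inheritParams icc_consistency
#' @return A ggplot.
#' @export
plot_correlation <- function(data, video = video, imu = imu) {
  df <- tibble::tibble(video = dplyr::pull(data, {{ video }}),
                       imu = dplyr::pull(data, {{ imu }}),
                       region = if ("region" %in% names(data)) data$region else "all")
  ggplot2::ggplot(df, ggplot2::aes(.data$imu, .data$video)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "IMU-derived", y = "Video-derived") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot straight from paired data
#'
#' Convenience wrapper: `autoplot(bland_altman(data, ...))`.
#'
#' @inheritParams icc_consistency
#' @return A ggplot.
#' @export
plot_bland_altman <- function(data, video = video, imu = imu) {
  autoplot(bland_altman(data, {{ video }}, {{ imu }}))
}
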