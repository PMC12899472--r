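#' Construct a 3-axis accelerometer recording
#'
#' @param ax,ay,az Numeric acceleration series (sensor units), equal length.
#' @param fs Sampling rate in Hz (nominal 100).
#' @param sensor_label Sensor placement label (e.g. `left_hand`,
#'   `right_hand`, `head`).
#' @return An `imu_recording` tibble with columns `time_s, ax, ay, az` and
#'   attributes `fs`, `sensor_label`.
#' @export
imu_recording <- function(ax, ay, az, fs = 100, sensor_label = NA_character_) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    abort_tc("Axis series ax, ay, az must have equal length.", "format")
  }
  if (!is_scalar_number(fs) || fs <= 0) abort_tc("`fs` must be positive.", "spec")
  out <- tibble::tibble(time_s = (seq_len(n) - 1L) / fs, ax = ax, ay = ay, az = az)
  structure(out, fs = fs, sensor_label = sensor_label,
            class = c("imu_recording", class(out)))
}

#' Read a 3-axis accelerometer CSV
#'
#' Expects at least the three configured numeric axis columns (default
#' `ax,ay,az`). Rows containing non-finite values in any axis are dropped
#' with a warning giving the count.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz (default 100; CSV exports carry no rate).
#' @param cols Names of the three axis columns.
#' @param sensor_label Optional placement label.
#' @return An `imu_recording`.
#' @export
load_imu_csv <- function(path, fs = 100, cols = c("ax", "ay", "az"),
                         sensor_label = NA_character_) {
  if (!file.exists(path)) abort_tc(sprintf("IMU file not found: %s", path), "format")
  stopifnot(length(cols) == 3L)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_tc(paste0("IMU CSV is missing axis column(s): ", paste(missing, collapse = ", ")),
             "format")
  }
  ax <- df[[cols[1]]]; ay <- df[[cols[2]]]; az <- df[[cols[3]]]
  if (!all(vapply(list(ax, ay, az), is.numeric, logical(1)))) {
    abort_tc("IMU axis columns must be numeric.", "format")
  }
  ok <- is.finite(ax) & is.finite(ay) & is.finite(az)
  if (!all(ok)) {
    rlang::warn(sprintf("Dropped %d row(s) with non-finite values from %s.",
                        sum(!ok), path))
  }
  if (sum(ok) < 16L) {
    abort_tc(sprintf("IMU recording has %d usable samples; at least 16 are required.",
                     sum(ok)), "too_short")
  }
  imu_recording(ax[ok], ay[ok], az[ok], fs = fs, sensor_label = sensor_label)
}

#' Write an accelerometer recording to CSV
#' @param rec An `imu_recording`.
#' @param path Output CSV path (columns `ax,ay,az`).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  readr::write_csv(rec[c("ax", "ay", "az")], path, progress = FALSE)
  invisible(path)
}

#' Tremor metrics from an accelerometer recording
#'
#' The reference-side pipeline: a Welch PSD per axis (each axis mean-removed,
#' which discards the gravity/DC component), L1 combination of the three axis
#' spectra, band restriction and peak extraction — the same spectral path as
#' the video side, with the same `floor(N / 8)` segmentation. Flicker
#' detection is not applied (lighting artifacts are video-specific).
#'
#' @param rec An `imu_recording`.
#' @param band `c(lo, hi)` analysis band in Hz (default 2-12).
#' @param segments Welch segmentation divisor (default 8).
#' @return A one-row tibble: `label`, `pp_db`, `ppf_hz`, `band_lo`,
#'   `band_hi`, with the combined spectrum in attribute `spectrum`.
#' @export
imu_metrics <- function(rec, band = c(2, 12), segments = 8L) {
  stopifnot(inherits(rec, "imu_recording"))
  fs <- attr(rec, "fs")
  check_band(band, fs = fs)
  spectra <- lapply(c("ax", "ay", "az"), function(a) {
    welch_psd(rec[[a]], fs = fs, segments = segments, label = a)
  })
  combined <- combine_psds_l1(spectra, label = attr(rec, "sensor_label"))
  out <- peak_metrics(combined, band = band, label = attr(rec, "sensor_label"))
  structure(out, spectrum = combined)
}
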