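#' Video-pipeline tremor metrics for a set of RoIs
#'
#' The full video path: per RoI a centre-of-mass motion trace
#' ([com_trace()]), Welch spectra of the two coordinate series combined by
#' the L1 norm (`combine = "psd"`, the default), or the time-domain L1
#' motion signal ([l1_combine_time()]) followed by a single Welch spectrum
#' (`combine = "time"`), then band restriction and peak extraction. With two
#' or more RoIs, shared narrow band-edge peaks are flagged as lighting
#' flicker ([detect_flicker()]); flagged peaks are recorded, not removed.
#'
#' @param clip A [video_clip].
#' @param rois RoI tibble (`label,x,y,width,height`), one row per region.
#' @param band `c(lo, hi)` analysis band in Hz (default 2-12).
#' @param combine `"psd"` (combine per-coordinate spectra; default) or
#'   `"time"` (combine coordinates in the time domain first).
#' @param norm Difference-frame normalisation, see [frame_difference()].
#' @param segments Welch segmentation divisor (default 8).
#' @param flicker Run flicker detection (default TRUE; needs >= 2 RoIs).
#' @param exclude_flagged Recompute metrics with flicker-flagged bins
#'   excluded (opt-in; default FALSE).
#' @return A tibble with one row per RoI: `roi_label`, `pp_db`, `ppf_hz`,
#'   `band_lo`, `band_hi`, `flicker_flagged`, `flicker_hz` (list-column).
#'   The per-RoI combined spectra are attached as attribute `spectra`.
#' @export
video_metrics <- function(clip, rois, band = c(2, 12), combine = c("psd", "time"),
                          norm = c("frame", "global"), segments = 8L,
                          flicker = TRUE, exclude_flagged = FALSE) {
  combine <- match.arg(combine)
  norm <- match.arg(norm)
  check_band(band, fs = clip$fps)
  check_roi_fields(rois)
  spectra <- purrr::map(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    trace <- com_trace(clip, r, norm = norm)
    if (combine == "psd") {
      sx <- welch_psd(trace$xc, fs = attr(trace, "fs"), segments = segments, label = "xc")
      sy <- welch_psd(trace$yc, fs = attr(trace, "fs"), segments = segments, label = "yc")
      combine_psds_l1(list(sx, sy), label = r$label)
    } else {
      welch_psd(l1_combine_time(trace), segments = segments, label = r$label)
    }
  })
  names(spectra) <- rois$label
  flags <- if (flicker && nrow(rois) >= 2L) {
    detect_flicker(spectra, band = band)
  } else {
    tibble::tibble(label = rois$label, flagged = FALSE,
                   flicker_hz = rep(list(numeric()), nrow(rois)))
  }
  out <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    excl <- if (exclude_flagged) flags$flicker_hz[[i]] else numeric()
    m <- peak_metrics(spectra[[i]], band = band, exclude_hz = excl,
                      label = rois$label[i])
    dplyr::mutate(dplyr::rename(m, roi_label = "label"),
                  flicker_flagged = flags$flagged[i],
                  flicker_hz = list(flags$flicker_hz[[i]]))
  })
  structure(out, spectra = spectra)
}

#' Default run configuration
#'
#' @return A named list: `band` (`lo` 2, `hi` 12 Hz), `welch$segments` (8),
#'   `combine` (`"psd"`), `norm` (`"frame"`), `flicker` (TRUE),
#'   `exclude_flagged` (FALSE), `imu` (`fs` 100, `cols` ax/ay/az), `trim`
#'   (`NULL`, or `list(start_s =, end_s =)`).
#' @export
default_config <- function() {
  list(band = list(lo = 2, hi = 12),
       welch = list(segments = 8L),
       combine = "psd",
       norm = "frame",
       flicker = TRUE,
       exclude_flagged = FALSE,
       imu = list(fs = 100, cols = c("ax", "ay", "az")),
       trim = NULL)
}

#' Load a YAML run configuration
#'
#' Keys present in the file override the defaults of [default_config()];
#' everything else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_tc(sprintf("Config file not found: %s", path), "format")
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_band <- function(config) c(config$band$lo, config$band$hi)

#' Run the video pipeline on one file
#'
#' Loads the video, applies any configured trim, validates every RoI against
#' the frame bounds and computes [video_metrics()]. When `out_dir` is given,
#' the metrics (`metrics_video.csv`), the per-RoI spectra (`spectra.csv`)
#' and the resolved configuration (`config.yaml`) are written there for
#' provenance; outputs are deterministic for identical inputs.
#'
#' @param video_path Path to the video (multi-page TIFF, see [load_video()]).
#' @param roi_csv Path to the RoI CSV (`label,x,y,width,height`).
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory.
#' @param fps Optional frame-rate override for containers without one.
#' @return The metrics tibble from [video_metrics()].
#' @export
run_video <- function(video_path, roi_csv, config = default_config(),
                      out_dir = NULL, fps = NULL) {
  clip <- load_video(video_path, fps = fps)
  if (!is.null(config$trim)) {
    clip <- trim_clip(clip, config$trim$start_s %||% 0, config$trim$end_s)
  }
  rois <- load_rois(roi_csv)
  if (nrow(rois) == 0L) abort_tc(sprintf("No RoIs in %s.", roi_csv), "format")
  for (i in seq_len(nrow(rois))) validate_roi(rois[i, ], clip)
  metrics <- video_metrics(clip, rois, band = config_band(config),
                           combine = config$combine, norm = config$norm,
                           segments = config$welch$segments,
                           flicker = isTRUE(config$flicker),
                           exclude_flagged = isTRUE(config$exclude_flagged))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- dplyr::mutate(metrics, flicker_hz = vapply(
      metrics$flicker_hz, function(v) paste(signif(v, 6), collapse = ";"), character(1)))
    readr::write_csv(flat, file.path(out_dir, "metrics_video.csv"), progress = FALSE)
    sp <- purrr::imap_dfr(attr(metrics, "spectra"), function(s, lab) {
      tibble::tibble(roi_label = lab, freq_hz = s$freq_hz, power = s$power)
    })
    readr::write_csv(sp, file.path(out_dir, "spectra.csv"), progress = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  }
  metrics
}

#' Run the IMU reference pipeline on one file
#'
#' @param imu_path Path to the accelerometer CSV.
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory (`metrics_imu.csv`).
#' @param sensor_label Placement label for the output row.
#' @return The one-row metrics tibble from [imu_metrics()].
#' @export
run_imu <- function(imu_path, config = default_config(), out_dir = NULL,
                    sensor_label = NA_character_) {
  rec <- load_imu_csv(imu_path, fs = config$imu$fs, cols = config$imu$cols,
                      sensor_label = sensor_label)
  if (!is.null(config$trim)) {
    fs <- attr(rec, "fs")
    i0 <- floor((config$trim$start_s %||% 0) * fs)
    i1 <- ceiling((config$trim$end_s %||% (nrow(rec) / fs)) * fs)
    rec <- imu_recording(rec$ax[(i0 + 1):i1], rec$ay[(i0 + 1):i1],
                         rec$az[(i0 + 1):i1], fs = fs, sensor_label = sensor_label)
  }
  metrics <- imu_metrics(rec, band = config_band(config),
                         segments = config$welch$segments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "metrics_imu.csv"), progress = FALSE)
  }
  metrics
}

#' Run the paired video-vs-IMU comparison over a cohort manifest
#'
#' For every manifest row both pipelines are run and the paired peak power
#' (PP, dB) and peak power frequency (PPF, Hz) are collected; the agreement
#' report (ICC with confidence interval, MAE, relative MAE, Bland-Altman
#' summary, descriptives) is assembled per metric. Manifest rows whose files
#' are missing are listed in a warning and excluded.
#'
#' @param manifest A manifest tibble or the path to a `manifest.csv` with
#'   columns `subject_id`, `video_path`, `imu_path`, `roi_path` (as written
#'   by [make_cohort()]).
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory: writes `paired_metrics.csv`,
#'   `agreement_report.csv` and the correlation / Bland-Altman panels
#'   (`correlation_<metric>.png`, `bland_altman_<metric>.png`).
#' @param region Region label to report (matched against RoI labels).
#' @return A list with `paired` (per-subject long tibble: `subject_id`,
#'   `region`, `metric`, `video`, `imu`) and `report` (per-metric agreement
#'   tibble, see [agreement_report()]).
#' @export
run_compare <- function(manifest, config = default_config(), out_dir = NULL,
                        region = NULL) {
  if (is.character(manifest)) manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  needed <- c("subject_id", "video_path", "imu_path", "roi_path")
  if (!all(needed %in% names(manifest))) {
    abort_tc(paste0("Manifest needs columns: ", paste(needed, collapse = ", ")), "format")
  }
  ok <- file.exists(manifest$video_path) & file.exists(manifest$imu_path) &
    file.exists(manifest$roi_path)
  if (!all(ok)) {
    rlang::warn(paste0("Excluding unpaired/missing subject(s): ",
                       paste(manifest$subject_id[!ok], collapse = ", ")))
    manifest <- manifest[ok, ]
  }
  paired <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vm <- run_video(row$video_path, row$roi_path, config = config)
    if (!is.null(region)) vm <- vm[vm$roi_label == region, ]
    purrr::map_dfr(seq_len(nrow(vm)), function(j) {
      im <- run_imu(row$imu_path, config = config, sensor_label = vm$roi_label[j])
      tibble::tibble(subject_id = row$subject_id,
                     region = vm$roi_label[j],
                     metric = c("PP", "PPF"),
                     video = c(vm$pp_db[j], vm$ppf_hz[j]),
                     imu = c(im$pp_db, im$ppf_hz))
    })
  })
  report <- agreement_report(paired, video, imu, groups = c("region", "metric"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(paired, file.path(out_dir, "paired_metrics.csv"), progress = FALSE)
    readr::write_csv(report, file.path(out_dir, "agreement_report.csv"), progress = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    for (m in unique(paired$metric)) {
      sub <- paired[paired$metric == m, ]
      ggplot2::ggsave(file.path(out_dir, paste0("correlation_", m, ".png")),
                      plot_correlation(sub, video, imu) +
                        ggplot2::facet_wrap(~region),
                      width = 7, height = 3.2, dpi = 120)
      ggplot2::ggsave(file.path(out_dir, paste0("bland_altman_", m, ".png")),
                      plot_bland_altman(sub, video, imu),
                      width = 5, height = 3.5, dpi = 120)
    }
  }
  list(paired = paired, report = report)
}
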