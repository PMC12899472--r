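#' Specify a synthetic oscillating blob
#'
#' A blob stands in for the moving body part inside an RoI: a bright profile
#' on a dark background whose centre oscillates sinusoidally at a known
#' frequency and pixel amplitude. Centres are continuous (sub-pixel): the
#' profile is evaluated at real-valued offsets so sinusoidal displacement
#' produces a clean spectral line.
#'
#' @param center `c(x, y)` blob centre in pixels (0-based, may be fractional).
#' @param radius Blob radius in pixels (for the Gaussian profile the standard
#'   deviation is `radius / 2`).
#' @param peak_intensity Peak intensity in `(0, 1]`.
#' @param osc_freq_hz Oscillation frequency (Hz); must lie below fps/2.
#' @param osc_amp_px Oscillation amplitude in pixels; 0 (static) or at least
#'   0.5 — sub-half-pixel motion is a sensitivity limit, not a supported
#'   regime.
#' @param osc_axis `"horizontal"`, `"vertical"` or `"both"`.
#' @param profile `"gaussian"` (default) or `"disc"` (antialiased hard edge).
#' @param phase Oscillation phase offset (radians).
#' @return A `blob_spec` list.
#' @export
blob_spec <- function(center, radius, peak_intensity = 0.8, osc_freq_hz = 5,
                      osc_amp_px = 4, osc_axis = c("horizontal", "vertical", "both"),
                      profile = c("gaussian", "disc"), phase = 0) {
  osc_axis <- match.arg(osc_axis)
  profile <- match.arg(profile)
  if (length(center) != 2L || !is.numeric(center)) {
    abort_tc("`center` must be c(x, y) in pixels.", "spec")
  }
  if (peak_intensity <= 0 || peak_intensity > 1) {
    abort_tc("`peak_intensity` must be in (0, 1].", "spec")
  }
  if (osc_amp_px != 0 && osc_amp_px < 0.5) {
    abort_tc("`osc_amp_px` must be 0 (static) or at least 0.5 pixels.", "spec")
  }
  structure(list(center = as.numeric(center), radius = radius,
                 peak_intensity = peak_intensity, osc_freq_hz = osc_freq_hz,
                 osc_amp_px = osc_amp_px, osc_axis = osc_axis,
                 profile = profile, phase = phase),
            class = "blob_spec")
}

#' Specify a synthetic scene
#'
#' Emulates the acquisition conditions of a seated tremor recording: a fixed
#' camera, plain dark background, 30 fps, around 20 s, with one bright blob
#' per tracked body part oscillating in the 2-12 Hz band. Optional additive
#' pixel noise and a rolling-shutter flicker artifact (see Details).
#'
#' Flicker from fluorescent lighting recorded through a CMOS rolling shutter
#' appears as horizontal intensity bands that drift vertically from frame to
#' frame. The generator renders this as a row-phased multiplicative
#' modulation `1 + depth * sin(pi * f * t / fps + 2 * pi * y / band_px)`.
#' Because frame differencing rectifies the banding, the drifting pattern
#' repeats — and the difference-frame centroid oscillates — at `freq_hz`,
#' i.e. `freq_hz` is the frequency of the artifact line the scene injects
#' into every RoI. (A spatially uniform modulation would leave the centroid
#' unmoved and produce no artifact at all.)
#'
#' @param duration_s Clip duration in seconds (default 20).
#' @param fps Frame rate (default 30).
#' @param frame_size `c(height, width)` in pixels.
#' @param blobs List of [blob_spec()] objects.
#' @param noise_sd SD of additive Gaussian pixel noise (intensity units);
#'   noise is added before clipping to `[0, 1]`.
#' @param background Background intensity in `[0, 1)` (default 0; flicker
#'   needs a non-zero background or blob to act on).
#' @param flicker `NULL`, or `list(freq_hz =, depth =, band_px =)` with
#'   `depth` in `[0, 1]`; `band_px` (vertical wavelength of the banding,
#'   default one frame height, i.e. one band visible per frame) controls how
#'   much of a band an RoI sees.
#' @param seed Integer RNG seed; scenes are bit-reproducible given the seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(duration_s = 20, fps = 30, frame_size = c(96, 96),
                       blobs = list(), noise_sd = 0.01, background = 0,
                       flicker = NULL, seed = 1L) {
  h <- frame_size[1]; w <- frame_size[2]
  for (b in blobs) {
    if (!inherits(b, "blob_spec")) abort_tc("`blobs` must be blob_spec objects.", "spec")
    if (b$osc_freq_hz >= fps / 2) {
      abort_tc(sprintf("Blob frequency %.3g Hz is not below Nyquist (%.3g Hz).",
                       b$osc_freq_hz, fps / 2), "spec")
    }
    ext <- b$radius + b$osc_amp_px
    if (b$center[1] - ext < 0 || b$center[1] + ext > w - 1 ||
        b$center[2] - ext < 0 || b$center[2] + ext > h - 1) {
      abort_tc("Blob leaves the frame at extreme displacement.", "spec")
    }
  }
  if (!is.null(flicker)) {
    if (is.null(flicker$freq_hz) || is.null(flicker$depth) ||
        flicker$depth < 0 || flicker$depth > 1) {
      abort_tc("`flicker` must be list(freq_hz =, depth in [0, 1]).", "spec")
    }
    flicker$band_px <- flicker$band_px %||% h
  }
  if (background < 0 || background >= 1) abort_tc("`background` must be in [0, 1).", "spec")
  structure(list(duration_s = duration_s, fps = fps, frame_size = c(h, w),
                 blobs = blobs, noise_sd = noise_sd, background = background,
                 flicker = flicker, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a synthetic scene to a clip with ground truth
#'
#' @param spec A [scene_spec()].
#' @return A list with `clip` (a [video_clip]) and `truth` (a tibble with one
#'   row per blob: `blob`, `freq_hz`, `amp_px`, `axis`, `center_x`,
#'   `center_y`, `radius`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  nt <- round(spec$duration_s * spec$fps)
  xv <- 0:(w - 1); yv <- 0:(h - 1)
  frames <- array(0, dim = c(h, w, nt))
  with_seed(spec$seed, {
    for (t in 0:(nt - 1)) {
      base <- matrix(spec$background, h, w)
      for (b in spec$blobs) {
        ph <- sin(2 * pi * b$osc_freq_hz * t / spec$fps + b$phase)
        cx <- b$center[1] + if (b$osc_axis != "vertical") b$osc_amp_px * ph else 0
        cy <- b$center[2] + if (b$osc_axis != "horizontal") b$osc_amp_px * ph else 0
        base <- base + blob_image(b, cx, cy, xv, yv)
      }
      if (!is.null(spec$flicker)) {
        fl <- spec$flicker
        mrow <- 1 + fl$depth * sin(pi * fl$freq_hz * t / spec$fps + 2 * pi * yv / fl$band_px)
        base <- base * mrow                       # row-wise banding
      }
      if (spec$noise_sd > 0) {
        base <- base + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      }
      frames[, , t + 1] <- pmin(pmax(base, 0), 1)
    }
  })
  truth <- purrr::imap_dfr(spec$blobs, function(b, i) {
    tibble::tibble(blob = i, freq_hz = b$osc_freq_hz, amp_px = b$osc_amp_px,
                   axis = b$osc_axis, center_x = b$center[1],
                   center_y = b$center[2], radius = b$radius)
  })
  list(clip = video_clip(frames, fps = spec$fps, source_path = "<synthetic>"),
       truth = truth)
}

blob_image <- function(b, cx, cy, xv, yv) {
  if (b$profile == "gaussian") {
    s2 <- 2 * (b$radius / 2)^2
    b$peak_intensity * outer(exp(-(yv - cy)^2 / s2), exp(-(xv - cx)^2 / s2))
  } else {
    d <- sqrt(outer((yv - cy)^2, (xv - cx)^2, `+`))
    b$peak_intensity * pmin(pmax(b$radius + 0.5 - d, 0), 1)
  }
}

#' Render a matched synthetic accelerometer trace
#'
#' Acceleration is the second derivative of the sinusoidal displacement,
#' `-(2 pi f)^2 * amp * sin(2 pi f t)`, distributed across the three axes by
#' a unit mixing vector, plus white noise and a constant gravity offset on
#' the z axis (removed downstream by per-axis mean removal).
#'
#' @param freq_hz Tremor frequency (Hz), below `fs / 2`.
#' @param amp_m Displacement amplitude in metres (default 0.005, a typical
#'   hand-tremor excursion of a few millimetres).
#' @param fs Sampling rate (Hz, default 100).
#' @param duration_s Duration in seconds (default 20).
#' @param noise_sd SD of additive white noise (m/s^2, default 0.1).
#' @param seed Integer RNG seed.
#' @param mixing Length-3 axis mixing vector (normalised internally).
#' @param gravity Constant offset added to the z axis (m/s^2).
#' @param sensor_label Placement label.
#' @param phase Oscillation phase offset (radians).
#' @return An `imu_recording`.
#' @export
render_imu <- function(freq_hz, amp_m = 0.005, fs = 100, duration_s = 20,
                       noise_sd = 0.1, seed = 1L, mixing = c(0.55, 0.6, 0.58),
                       gravity = 9.81, sensor_label = NA_character_, phase = 0) {
  if (freq_hz >= fs / 2) abort_tc("`freq_hz` must be below the Nyquist frequency.", "spec")
  u <- mixing / sqrt(sum(mixing^2))
  n <- round(duration_s * fs)
  tt <- (0:(n - 1)) / fs
  a <- -(2 * pi * freq_hz)^2 * amp_m * sin(2 * pi * freq_hz * tt + phase)
  with_seed(seed, {
    ax <- u[1] * a + stats::rnorm(n, 0, noise_sd)
    ay <- u[2] * a + stats::rnorm(n, 0, noise_sd)
    az <- u[3] * a + stats::rnorm(n, 0, noise_sd) + gravity
  })
  imu_recording(ax, ay, az, fs = fs, sensor_label = sensor_label)
}

#' Generate a paired video + IMU cohort with ground truth
#'
#' Emulates a validation cohort: per subject a tremor frequency and amplitude
#' are drawn, one synthetic scene (single centred blob) and one matched
#' accelerometer trace are generated from the same ground truth, and
#' everything is written to disk — videos (8-bit multi-page TIFF, matching
#' the bit depth of consumer video), IMU CSVs, RoI CSVs and a manifest.
#'
#' @param n_subjects Number of subjects (>= 3; default 30).
#' @param out_dir Output directory (created if needed).
#' @param freq_range Tremor frequency range in Hz (default `c(3, 9)`).
#' @param amp_range Blob oscillation amplitude range in pixels.
#' @param noise_sd Pixel noise SD for the scenes.
#' @param imu_noise_sd Accelerometer noise SD (m/s^2).
#' @param duration_s,fps,frame_size Scene geometry (defaults 20 s, 30 fps,
#'   96 x 96 px).
#' @param region Region label used for the RoI and sensor.
#' @param px_to_m Pixel-to-metre factor linking blob amplitude to IMU
#'   displacement amplitude (default 0.001: about 1 mm per pixel at a ~2 m
#'   camera distance).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return The manifest tibble (`subject_id`, `true_freq_hz`, `true_amp_px`,
#'   `video_path`, `imu_path`, `roi_path`), also written to
#'   `out_dir/manifest.csv`.
#' @export
make_cohort <- function(n_subjects = 30, out_dir, freq_range = c(3, 9),
                        amp_range = c(2, 6), noise_sd = 0.01, imu_noise_sd = 0.1,
                        duration_s = 20, fps = 30, frame_size = c(96, 96),
                        region = "right_hand", px_to_m = 0.001, seed = 1L) {
  if (n_subjects < 3) abort_tc("A cohort needs at least 3 subjects.", "spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- frame_size[1]; w <- frame_size[2]
  draws <- with_seed(seed, list(
    freq = stats::runif(n_subjects, freq_range[1], freq_range[2]),
    amp = stats::runif(n_subjects, amp_range[1], amp_range[2]),
    phase = stats::runif(n_subjects, 0, 2 * pi),
    sub_seed = sample.int(.Machine$integer.max - 1L, 2L * n_subjects)
  ))
  radius <- 8
  rows <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    id <- sprintf("s%02d", i)
    sc <- scene_spec(duration_s = duration_s, fps = fps, frame_size = frame_size,
                     blobs = list(blob_spec(center = c((w - 1) / 2, (h - 1) / 2),
                                            radius = radius,
                                            osc_freq_hz = draws$freq[i],
                                            osc_amp_px = draws$amp[i],
                                            phase = draws$phase[i])),
                     noise_sd = noise_sd, seed = draws$sub_seed[2 * i - 1])
    scene <- render_scene(sc)
    video_path <- file.path(out_dir, paste0(id, "_video.tif"))
    write_video(scene$clip, video_path, bits = 8L)
    rec <- render_imu(draws$freq[i], amp_m = draws$amp[i] * px_to_m,
                      duration_s = duration_s, noise_sd = imu_noise_sd,
                      seed = draws$sub_seed[2 * i], sensor_label = region,
                      phase = draws$phase[i])
    imu_path <- file.path(out_dir, paste0(id, "_imu.csv"))
    write_imu_csv(rec, imu_path)
    half <- ceiling(radius * 1.5 + amp_range[2]) + 2L
    x0 <- max(0L, floor((w - 1) / 2) - half)
    y0 <- max(0L, floor((h - 1) / 2) - half)
    r <- roi(region, x0, y0, min(2L * half + 1L, w - x0), min(2L * half + 1L, h - y0))
    roi_path <- file.path(out_dir, paste0(id, "_roi.csv"))
    write_rois(r, roi_path)
    tibble::tibble(subject_id = id, true_freq_hz = draws$freq[i],
                   true_amp_px = draws$amp[i], video_path = video_path,
                   imu_path = imu_path, roi_path = roi_path)
  })
  readr::write_csv(rows, file.path(out_dir, "manifest.csv"), progress = FALSE)
  rows
}
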