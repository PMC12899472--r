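#' Absolute frame differences over an RoI
#'
#' For each consecutive frame pair the RoI crops are subtracted, the absolute
#' value taken, and the result normalised to `[0, 1]`. Only changed (moving)
#' pixels carry intensity, so the static background drops out. Normalisation
#' is per difference frame by default (min-max within each frame, which makes
#' the downstream centroid invariant to global intensity scaling); `"global"`
#' instead divides every frame by the clip-wide maximum difference. A pair
#' whose difference is constant (max equals min) yields an all-zero frame and
#' is flagged degenerate.
#'
#' @param clip A [video_clip].
#' @param roi Optional one-row RoI tibble; `NULL` uses the full frame.
#' @param norm `"frame"` (per-difference min-max, default) or `"global"`.
#' @return A `diff_stack`: list with `values` (array
#'   `[height, width, n_frames - 1]`, entries in `[0, 1]`), `degenerate`
#'   (logical per pair) and `frame_index` (1-based index of the later frame
#'   of each pair).
#' @export
frame_difference <- function(clip, roi = NULL, norm = c("frame", "global")) {
  stopifnot(inherits(clip, "video_clip"))
  norm <- match.arg(norm)
  if (!is.null(roi)) clip <- crop_roi(clip, roi)
  f <- clip$frames
  nt <- dim(f)[3]
  d <- abs(f[, , 2:nt, drop = FALSE] - f[, , 1:(nt - 1), drop = FALSE])
  npair <- nt - 1L
  m <- matrix(d, ncol = npair)                     # pixels x pairs
  mins <- apply(m, 2L, min)
  maxs <- apply(m, 2L, max)
  degenerate <- maxs <= mins
  if (norm == "frame") {
    scale <- ifelse(degenerate, 1, maxs - mins)
    m <- sweep(sweep(m, 2L, mins, "-"), 2L, scale, "/")
    m[, degenerate] <- 0
  } else {
    gmax <- max(maxs)
    if (gmax > 0) m <- m / gmax
    m[, degenerate] <- 0
  }
  structure(list(values = array(m, dim = dim(d)),
                 degenerate = degenerate,
                 frame_index = 2:nt),
            class = "diff_stack")
}

#' Intensity-weighted centre of mass of a difference image
#'
#' Pixel intensities are treated as masses; the centroid is the weighted
#' average of the 0-based pixel coordinates:
#' `xc = sum(x * I(x, y)) / sum(I)`, `yc = sum(y * I(x, y)) / sum(I)`.
#'
#' @param values A non-negative numeric matrix (rows are `y`, columns `x`).
#' @return Named numeric vector `c(xc = , yc = )` in 0-based RoI-local
#'   pixels. Errors on an all-zero (degenerate) image; callers that walk a
#'   whole clip apply a hold-last-value policy instead (see [com_trace()]).
#' @export
center_of_mass <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  total <- sum(values)
  if (!is.finite(total) || total <= 0) {
    abort_tc("Centre of mass is undefined for an all-zero (degenerate) image.", "degenerate")
  }
  xs <- 0:(ncol(values) - 1L)
  ys <- 0:(nrow(values) - 1L)
  c(xc = sum(colSums(values) * xs) / total,
    yc = sum(rowSums(values) * ys) / total)
}

#' Centre-of-mass motion trace of an RoI
#'
#' Runs [frame_difference()] and the weighted centroid over every consecutive
#' frame pair, producing the motion time series sampled at the video frame
#' rate. Degenerate pairs (no intensity change at all) carry the previous
#' centroid forward; if the first pair is degenerate the RoI geometric centre
#' `((width - 1) / 2, (height - 1) / 2)` is used, so a fully static scene
#' gives a constant trace.
#'
#' @inheritParams frame_difference
#' @return A `motion_trace` tibble with columns `frame_index` (later frame of
#'   each pair, 1-based), `time_s`, `xc`, `yc` (RoI-local 0-based pixels) and
#'   `degenerate`; attributes `fs` (Hz), `roi_label`, `roi_width`,
#'   `roi_height`. Length is `n_frames - 1`.
#' @export
com_trace <- function(clip, roi = NULL, norm = c("frame", "global")) {
  norm <- match.arg(norm)
  label <- if (!is.null(roi)) roi$label else "full_frame"
  ds <- frame_difference(clip, roi, norm)
  dm <- dim(ds$values)
  h <- dm[1]; w <- dm[2]; npair <- dm[3]
  m <- matrix(ds$values, ncol = npair)
  xs <- rep(0:(w - 1L), each = h)
  ys <- rep(0:(h - 1L), times = w)
  tot <- colSums(m)
  xc <- as.vector(crossprod(m, xs)) / tot
  yc <- as.vector(crossprod(m, ys)) / tot
  # hold-last-value over degenerate pairs; geometric centre before first motion
  xc[ds$degenerate] <- NA_real_
  yc[ds$degenerate] <- NA_real_
  xc <- fill_forward(xc, (w - 1) / 2)
  yc <- fill_forward(yc, (h - 1) / 2)
  out <- tibble::tibble(frame_index = ds$frame_index,
                        time_s = (ds$frame_index - 1L) / clip$fps,
                        xc = xc, yc = yc, degenerate = ds$degenerate)
  structure(out, fs = clip$fps, roi_label = label, roi_width = w, roi_height = h,
            class = c("motion_trace", class(out)))
}

fill_forward <- function(x, first) {
  if (is.na(x[1])) x[1] <- first
  idx <- cumsum(!is.na(x))
  x[!is.na(x)][pmax(idx, 1L)]
}

#' Collapse a motion trace to a scalar motion signal (time-domain L1)
#'
#' Mean-centres the two coordinate series and sums their absolute values:
#' `value[t] = |xc[t] - mean(xc)| + |yc[t] - mean(yc)|`. Centring makes the
#' signal invariant to any constant offset of the trace; note that full-wave
#' rectification moves the energy of a pure sinusoidal oscillation to twice
#' the driving frequency, which is why the spectral pipeline's default
#' combines the per-coordinate spectra instead (see [video_metrics()]).
#'
#' @param trace A `motion_trace` from [com_trace()].
#' @return A `motion_signal` tibble with columns `frame_index`, `time_s`,
#'   `value` (non-negative), same length and `fs` as the trace.
#' @export
l1_combine_time <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  value <- abs(trace$xc - mean(trace$xc)) + abs(trace$yc - mean(trace$yc))
  out <- tibble::tibble(frame_index = trace$frame_index,
                        time_s = trace$time_s, value = value)
  structure(out, fs = attr(trace, "fs"), roi_label = attr(trace, "roi_label"),
            class = c("motion_signal", class(out)))
}
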