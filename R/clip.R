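#' Construct a video clip
#'
#' A `video_clip` holds a stack of grayscale frames as a 3-D array indexed
#' `[row, column, frame]` with intensities in `[0, 1]`, together with the
#' frame rate. Pixel coordinates throughout the package are 0-based with the
#' origin at the top-left corner: `x` runs along columns, `y` along rows.
#'
#' @param frames A numeric 3-D array `[height, width, n_frames]`, or a list
#'   of equally sized matrices.
#' @param fps Frames per second (Hz), positive.
#' @param source_path Optional provenance string.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, fps, source_path = NA_character_) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) abort_tc("All frames must share the same height/width.", "decode")
    frames <- array(unlist(frames, use.names = FALSE), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort_tc("`frames` must be a [height, width, n_frames] array or a list of matrices.", "decode")
  }
  if (!is_scalar_number(fps) || fps <= 0) abort_tc("`fps` must be a positive number.", "spec")
  if (dim(frames)[3] < 2L) {
    abort_tc("A clip needs at least 2 frames for frame differencing.", "insufficient_frames")
  }
  rng <- range(frames)
  if (anyNA(frames) || rng[1] < 0 || rng[2] > 1) {
    abort_tc("Frame intensities must be finite and within [0, 1].", "decode")
  }
  structure(list(frames = frames, fps = fps, source_path = source_path),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d frames, %dx%d px, %.3g fps (%.2f s)\n",
              d[3], d[2], d[1], x$fps, d[3] / x$fps))
  invisible(x)
}

#' @export
dim.video_clip <- function(x) dim(x$frames)

n_frames <- function(clip) dim(clip$frames)[3]
frame_height <- function(clip) dim(clip$frames)[1]
frame_width <- function(clip) dim(clip$frames)[2]

#' Clip duration in seconds
#' @param clip A [video_clip].
#' @return Duration in seconds (`n_frames / fps`).
#' @export
clip_duration <- function(clip) n_frames(clip) / clip$fps

#' Read a video file into a grayscale clip
#'
#' Reads a multi-page TIFF stack (the package's video container; lossless, so
#' synthetic scenes round-trip numerically). Colour pages are converted to
#' luminance with Rec. 709 weights (0.2126 R + 0.7152 G + 0.0722 B). The
#' frame rate is taken from a JSON sidecar `<path>.json` written by
#' [write_video()]; an explicit `fps` argument overrides it (useful for
#' stacks produced elsewhere).
#'
#' @param path Path to a multi-page TIFF file.
#' @param fps Optional frame-rate override (Hz).
#' @return A [video_clip].
#' @export
load_video <- function(path, fps = NULL) {
  if (!file.exists(path)) abort_tc(sprintf("Video file not found: %s", path), "decode")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) abort_tc(
                      sprintf("Could not decode %s: %s", path, conditionMessage(e)), "decode"))
  if (is.array(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    abort_tc(sprintf("%s has %d frame(s); at least 2 are required.", path, length(pages)),
             "insufficient_frames")
  }
  pages <- lapply(pages, to_gray)
  if (is.null(fps)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      fps <- meta$fps
    }
  }
  if (is.null(fps)) {
    abort_tc(sprintf("No frame rate for %s: provide `fps` or a `%s.json` sidecar.", path, path),
             "decode")
  }
  video_clip(pages, fps = fps, source_path = path)
}

to_gray <- function(page) {
  if (length(dim(page)) == 2L) return(pmin(pmax(page, 0), 1))
  nc <- dim(page)[3]
  w <- if (nc >= 3) c(0.2126, 0.7152, 0.0722) else rep(1 / nc, nc)
  g <- matrix(0, nrow(page), ncol(page))
  for (i in seq_along(w)) g <- g + w[i] * page[, , i]
  pmin(pmax(g, 0), 1)
}

#' Write a clip to a multi-page TIFF with an fps sidecar
#'
#' Frames are stored as 32-bit float TIFF pages (lossless for the `[0, 1]`
#' intensities used here); the frame rate goes into a `<path>.json` sidecar
#' because TIFF has no frame-rate tag.
#'
#' @param clip A [video_clip].
#' @param path Output path (`.tif`).
#' @param bits Bits per sample (8, 16 or 32; 32 is float and lossless).
#' @return `path`, invisibly.
#' @export
write_video <- function(clip, path, bits = 32L) {
  stopifnot(inherits(clip, "video_clip"))
  pages <- lapply(seq_len(n_frames(clip)), function(t) clip$frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  jsonlite::write_json(list(fps = clip$fps), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Trim a clip to a time window
#'
#' Keeps the sub-clip covering `[start_s, end_s)`. Boundaries are mapped to
#' frame indices by rounding the start down and the end up at frame
#' granularity, so the kept span always covers the requested interval;
#' the result must retain at least 2 frames.
#'
#' @param clip A [video_clip].
#' @param start_s Start time in seconds from the beginning of the clip.
#' @param end_s End time in seconds (exclusive); `NULL` means clip end.
#' @return A trimmed [video_clip].
#' @export
trim_clip <- function(clip, start_s = 0, end_s = NULL) {
  stopifnot(inherits(clip, "video_clip"))
  dur <- clip_duration(clip)
  end_s <- end_s %||% dur
  if (!is_scalar_number(start_s) || !is_scalar_number(end_s) ||
      start_s < 0 || start_s >= end_s || end_s > dur + 1e-9) {
    abort_tc(sprintf("Trim window [%.3g, %.3g) must satisfy 0 <= start < end <= %.3g s.",
                     start_s, end_s, dur), "spec")
  }
  i0 <- floor(start_s * clip$fps)                  # 0-based first frame kept
  i1 <- min(ceiling(end_s * clip$fps), n_frames(clip))  # 0-based exclusive end
  if (i1 - i0 < 2L) {
    abort_tc("Trim window keeps fewer than 2 frames.", "insufficient_frames")
  }
  video_clip(clip$frames[, , (i0 + 1L):i1, drop = FALSE], fps = clip$fps,
             source_path = clip$source_path)
}
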