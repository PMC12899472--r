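#' Rectangular regions of interest
#'
#' An RoI is a rectangle fixed for the whole video, stored in pixel
#' coordinates: 0-based, top-left origin, half-open on both axes, i.e. it
#' covers columns `[x, x + width)` and rows `[y, y + height)`. RoI sets are
#' plain tibbles with columns `label, x, y, width, height`, one row per
#' region (typical labels: `left_hand`, `right_hand`, `head`).
#'
#' @param label Region label.
#' @param x,y Top-left corner (pixels, 0-based integers).
#' @param width,height Extent in pixels (integers, each at least 2).
#' @return A one-row tibble with columns `label, x, y, width, height`.
#' @export
roi <- function(label, x, y, width, height) {
  out <- tibble::tibble(label = as.character(label),
                        x = x, y = y, width = width, height = height)
  check_roi_fields(out)
  out
}

check_roi_fields <- function(rois) {
  needed <- c("label", "x", "y", "width", "height")
  missing <- setdiff(needed, names(rois))
  if (length(missing)) {
    abort_tc(paste0("RoI table is missing column(s): ", paste(missing, collapse = ", ")),
             "format")
  }
  if (nrow(rois) > 0L) {
    num <- rois[c("x", "y", "width", "height")]
    if (!all(vapply(num, is.numeric, logical(1))) || anyNA(num) ||
        !all(vapply(num, function(v) all(v == floor(v)), logical(1)))) {
      abort_tc("RoI coordinates x, y, width, height must be integer pixels.", "format")
    }
    if (any(rois$width < 2) || any(rois$height < 2)) {
      abort_tc("RoI width and height must each be at least 2 pixels.", "format")
    }
  }
  invisible(rois)
}

#' Read RoIs from CSV
#'
#' Expects a header `label,x,y,width,height` with integer pixel coordinates,
#' one region per row. Validation against a particular clip's frame size is
#' separate: see [validate_roi()].
#'
#' @param path CSV file path.
#' @return A tibble of RoIs (possibly zero rows) in file order.
#' @export
load_rois <- function(path) {
  if (!file.exists(path)) abort_tc(sprintf("RoI file not found: %s", path), "format")
  rois <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_roi_fields(rois)
  dplyr::mutate(rois, dplyr::across(c("x", "y", "width", "height"), as.integer))
}

#' Write RoIs to CSV
#' @param rois RoI tibble (`label,x,y,width,height`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  check_roi_fields(rois)
  readr::write_csv(rois[c("label", "x", "y", "width", "height")], path, progress = FALSE)
  invisible(path)
}

#' Check that an RoI lies fully inside a clip's frames
#'
#' Accepts exactly the rectangles with `x >= 0`, `y >= 0`,
#' `x + width <= frame width`, `y + height <= frame height` (half-open
#' convention, so a rectangle flush with the bottom-right corner is valid).
#'
#' @param roi A one-row RoI tibble.
#' @param clip A [video_clip].
#' @return `roi`, unchanged, if valid; otherwise an out-of-bounds error
#'   naming the offending edge.
#' @export
validate_roi <- function(roi, clip) {
  check_roi_fields(roi)
  stopifnot(nrow(roi) == 1L, inherits(clip, "video_clip"))
  W <- frame_width(clip); H <- frame_height(clip)
  bad <- c(
    if (roi$x < 0) "left edge (x < 0)",
    if (roi$y < 0) "top edge (y < 0)",
    if (roi$x + roi$width > W) sprintf("right edge (x + width = %d > frame width %d)",
                                       roi$x + roi$width, W),
    if (roi$y + roi$height > H) sprintf("bottom edge (y + height = %d > frame height %d)",
                                        roi$y + roi$height, H)
  )
  if (length(bad)) {
    abort_tc(sprintf("RoI '%s' lies outside the frame: %s.",
                     roi$label, paste(bad, collapse = "; ")), "out_of_bounds")
  }
  roi
}

#' Crop a clip to an RoI
#' @param clip A [video_clip].
#' @param roi A one-row RoI tibble (validated against `clip`).
#' @return A [video_clip] restricted to the RoI rectangle.
#' @export
crop_roi <- function(clip, roi) {
  roi <- validate_roi(roi, clip)
  rows <- (roi$y + 1L):(roi$y + roi$height)
  cols <- (roi$x + 1L):(roi$x + roi$width)
  video_clip(clip$frames[rows, cols, , drop = FALSE], fps = clip$fps,
             source_path = clip$source_path)
}
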