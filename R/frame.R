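#' A single RGB frame of an elastography clip
#'
#' Wraps an `H x W x 3` array of 8-bit channel values together with the
#' frame's temporal index. Frames are the raw pixel substrate every other
#' operation works on; each frame of a clip is analyzed individually, without
#' temporal averaging.
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`.
#' @param index Frame number, zero-based, `>= 0`.
#' @return An object of class `sweclip_frame`.
#' @export
frame_image <- function(pixels, index = 0L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an H x W x 3 array")
  }
  d <- dim(pixels)
  if (d[1] < 32L || d[2] < 32L) {
    stop("frame must be at least 32 x 32 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  if (!is.numeric(index) || length(index) != 1L || index < 0 ||
      index != round(index)) {
    stop("index must be a single integer >= 0")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, index = as.integer(index)),
            class = "sweclip_frame")
}

#' @export
print.sweclip_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sweclip_frame> %d x %d px, frame index %d\n",
              d[1], d[2], x$index))
  invisible(x)
}

frame_dim <- function(frame) dim(frame$pixels)[1:2]

# Crop a frame's pixels to a px_rect, keeping the 3 channels.
crop_pixels <- function(frame, rect) {
  d <- frame_dim(frame)
  if (!rect_inside(rect, d[1], d[2])) {
    stop("rectangle lies outside the frame")
  }
  frame$pixels[rect_row_idx(rect), rect_col_idx(rect), , drop = FALSE]
}
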