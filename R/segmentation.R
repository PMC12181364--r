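#' Elastogram geometry
#'
#' The elastogram's bounding box inside a frame (half-open [px_rect()])
#' together with the physical scale in mm per pixel and how the geometry was
#' obtained. The geometry from one reference frame is applied to every frame
#' of a clip, so the analyzed region stays consistent over time.
#'
#' @param box A `px_rect` (interior of the elastogram, excluding the frame
#'   line).
#' @param mm_per_px Physical scale, mm per pixel, `> 0`.
#' @param mode `"auto"` or `"manual"`.
#' @param frame Optional [frame_image()] used to bounds-check the box.
#' @return Object of class `sweclip_geometry`.
#' @export
elastogram_geometry <- function(box, mm_per_px, mode = c("auto", "manual"),
                                frame = NULL) {
  mode <- match.arg(mode)
  if (!inherits(box, "px_rect")) stop("box must be a px_rect")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0) {
    stop("mm_per_px must be a single positive number")
  }
  if (!is.null(frame)) {
    d <- frame_dim(frame)
    if (!rect_inside(box, d[1], d[2])) stop("box lies outside the frame")
  }
  structure(list(box = box, mm_per_px = as.numeric(mm_per_px), mode = mode),
            class = "sweclip_geometry")
}

#' @export
print.sweclip_geometry <- function(x, ...) {
  cat(sprintf("<sweclip_geometry> %s, %g mm/px, mode %s\n",
              format(x$box), x$mm_per_px, x$mode))
  invisible(x)
}

#' Manually specified geometry
#'
#' Fallback when automatic segmentation fails or is not satisfactory: the box
#' and scale are passed through unchanged with `mode = "manual"`.
#'
#' @inheritParams elastogram_geometry
#' @export
manual_geometry <- function(box, mm_per_px, frame = NULL) {
  elastogram_geometry(box, mm_per_px, mode = "manual", frame = frame)
}

segmentation_error <- function(msg) {
  stop(structure(class = c("sweclip_segmentation_error", "error", "condition"),
                 list(message = paste0(
                   msg, " Segment the image manually (manual_geometry()) ",
                   "with an explicit box and mm_per_px."),
                   call = NULL)))
}

scale_error <- function(msg) {
  stop(structure(class = c("sweclip_scale_error", "error", "condition"),
                 list(message = paste0(
                   msg, " Supply mm_per_px manually."), call = NULL)))
}

# Pixel mask matching a frame-line color spec.
# Exported clips draw an orange line around the elastogram; single-image
# exports draw a white one. Defaults are far from both grayscale B-mode and
# the colormap hues, and overridable via list(rgb = c(r,g,b), tol = t).
frame_line_mask <- function(pixels, frame_line) {
  r <- pixels[, , 1]; g <- pixels[, , 2]; b <- pixels[, , 3]
  if (is.character(frame_line)) {
    switch(match.arg(frame_line, c("orange", "white")),
           orange = r >= 200 & g >= 80 & g <= 180 & b <= 80,
           white = r >= 245 & g >= 245 & b >= 245)
  } else if (is.list(frame_line) && !is.null(frame_line$rgb)) {
    tol <- if (is.null(frame_line$tol)) 10 else frame_line$tol
    abs(r - frame_line$rgb[1]) <= tol & abs(g - frame_line$rgb[2]) <= tol &
      abs(b - frame_line$rgb[3]) <= tol
  } else {
    stop("frame_line must be 'orange', 'white', or list(rgb=, tol=)")
  }
}

#' Detect the elastogram box from its colored frame line
#'
#' Finds connected components of pixels matching the frame-line color, keeps
#' the largest component that forms a ring (at least `min_perimeter_cover` of
#' its bounding-box perimeter matched, which rejects spurious colored text),
#' estimates the per-side line width, and returns the interior rectangle —
#' the line itself is excluded.
#'
#' @param frame A [frame_image()].
#' @param frame_line `"orange"` (clip exports), `"white"` (single-image
#'   exports), or `list(rgb = c(r, g, b), tol = t)`.
#' @param min_perimeter_cover Minimum matched fraction of the component's
#'   bounding-box perimeter for ring validation.
#' @return Interior `px_rect`.
#' @export
detect_elastogram_box <- function(frame, frame_line = "orange",
                                  min_perimeter_cover = 0.9) {
  mask <- frame_line_mask(frame$pixels, frame_line)
  if (!any(mask)) {
    segmentation_error("No pixels matching the frame-line color were found.")
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  for (id in order(sizes, decreasing = TRUE)) {
    comp <- lab == id
    rows <- range(which(rowSums(comp) > 0))
    cols <- range(which(colSums(comp) > 0))
    top <- comp[rows[1], cols[1]:cols[2]]
    bottom <- comp[rows[2], cols[1]:cols[2]]
    left <- comp[rows[1]:rows[2], cols[1]]
    right <- comp[rows[1]:rows[2], cols[2]]
    cover <- mean(c(top, bottom, left, right))
    if (cover < min_perimeter_cover) next

    # per-side line width: consecutive fully matched border rows/columns
    run <- function(v) {
      w <- 0L
      for (x in v) { if (x) w <- w + 1L else break }
      w
    }
    band_frac <- 0.9
    w_top <- run(vapply(rows[1]:rows[2], function(rw)
      mean(comp[rw, cols[1]:cols[2]]) >= band_frac, logical(1)))
    w_bottom <- run(vapply(rows[2]:rows[1], function(rw)
      mean(comp[rw, cols[1]:cols[2]]) >= band_frac, logical(1)))
    w_left <- run(vapply(cols[1]:cols[2], function(cl)
      mean(comp[rows[1]:rows[2], cl]) >= band_frac, logical(1)))
    w_right <- run(vapply(cols[2]:cols[1], function(cl)
      mean(comp[rows[1]:rows[2], cl]) >= band_frac, logical(1)))
    w_top <- max(w_top, 1L); w_bottom <- max(w_bottom, 1L)
    w_left <- max(w_left, 1L); w_right <- max(w_right, 1L)

    row0 <- (rows[1] - 1L) + w_top
    row1 <- rows[2] - w_bottom
    col0 <- (cols[1] - 1L) + w_left
    col1 <- cols[2] - w_right
    if (row1 <= row0 || col1 <= col0) next
    return(px_rect(row0, row1, col0, col1))
  }
  segmentation_error("No connected ring of frame-line-colored pixels found.")
}

#' Calibrate physical scale from the measurement bar
#'
#' Detects tick marks as local maxima of the brightness profile along the
#' configured ruler column band and converts the median inter-tick spacing in
#' pixels into mm per pixel.
#'
#' @param frame A [frame_image()].
#' @param ruler_region `px_rect` containing the measurement bar.
#' @param tick_interval_mm Physical distance between consecutive ticks (mm).
#' @return `mm_per_px` (scalar).
#' @export
detect_scale <- function(frame, ruler_region, tick_interval_mm = 10) {
  if (tick_interval_mm <= 0) stop("tick_interval_mm must be > 0")
  px <- crop_pixels(frame, ruler_region)
  profile <- rowMeans(px[, , 1] + px[, , 2] + px[, , 3]) / 3
  rng <- range(profile)
  if (diff(rng) < 20) {
    scale_error("No tick marks found in the ruler region (flat profile).")
  }
  thr <- mean(rng)
  hot <- profile > thr
  # cluster consecutive hot rows into tick centers
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  centers <- (starts[runs$values] + ends[runs$values]) / 2
  if (length(centers) < 2L) {
    scale_error("Fewer than 2 tick marks detected in the ruler region.")
  }
  tick_interval_mm / stats::median(diff(centers))
}

#' Automatic geometry from a reference frame
#'
#' Runs [detect_elastogram_box()] and [detect_scale()] on one reference frame
#' and packages the result. The same geometry is then used for every frame of
#' the clip.
#'
#' @inheritParams detect_elastogram_box
#' @inheritParams detect_scale
#' @return A `sweclip_geometry` with `mode = "auto"`.
#' @export
detect_geometry <- function(frame, ruler_region, frame_line = "orange",
                            tick_interval_mm = 10) {
  box <- detect_elastogram_box(frame, frame_line)
  mpp <- detect_scale(frame, ruler_region, tick_interval_mm)
  elastogram_geometry(box, mpp, mode = "auto", frame = frame)
}
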