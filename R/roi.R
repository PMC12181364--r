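#' ROI masks
#'
#' Analysis regions inside the elastogram box: either a hand-specified
#' rectangle given in mm relative to the box's top-left corner, or a tiling
#' of square grid cells (default 4 x 4 mm). A mask is a logical matrix
#' matching the box; grid cells additionally carry an integer `cell_id` label
#' per pixel (0 = outside all cells).
#'
#' @name roi_mask
NULL

new_roi_mask <- function(mask, cell_id = NULL, kind) {
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(mask = mask, cell_id = cell_id, kind = kind),
            class = "sweclip_roi")
}

#' @export
print.sweclip_roi <- function(x, ...) {
  cat(sprintf("<sweclip_roi> %s, %d x %d px, %d px selected",
              x$kind, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  if (!is.null(x$cell_id)) cat(sprintf(", %d cells", max(x$cell_id)))
  cat("\n")
  invisible(x)
}

#' Rectangular ROI mask
#'
#' Converts a physical rectangle `(x0, y0, width, height)` in mm — measured
#' from the elastogram box's top-left corner, x rightwards, y downwards —
#' into a pixel mask. Edges are rounded to the nearest pixel edge; a pixel is
#' included iff its center falls inside the rounded rectangle.
#'
#' @param geom An [elastogram_geometry()].
#' @param rect_mm Numeric `c(x0, y0, width, height)` in mm.
#' @return A `sweclip_roi` of kind `"rectangle"`.
#' @export
build_rect_mask <- function(geom, rect_mm) {
  if (length(rect_mm) != 4L || anyNA(rect_mm)) {
    stop("rect_mm must be c(x0, y0, width, height) in mm")
  }
  x0 <- rect_mm[1]; y0 <- rect_mm[2]; w <- rect_mm[3]; h <- rect_mm[4]
  if (x0 < 0 || y0 < 0 || w <= 0 || h <= 0) {
    stop("rectangle must be non-negative with positive width and height")
  }
  mpp <- geom$mm_per_px
  H <- rect_height(geom$box); W <- rect_width(geom$box)
  eps <- 1e-9
  if (x0 + w > W * mpp + eps || y0 + h > H * mpp + eps) {
    stop("rectangle extends past the elastogram box")
  }
  c0 <- round(x0 / mpp); c1 <- round((x0 + w) / mpp)
  r0 <- round(y0 / mpp); r1 <- round((y0 + h) / mpp)
  c1 <- min(c1, W); r1 <- min(r1, H)
  if (r1 <= r0 || c1 <= c0) stop("rectangle rounds to an empty pixel set")
  mask <- matrix(FALSE, H, W)
  mask[(r0 + 1):r1, (c0 + 1):c1] <- TRUE
  new_roi_mask(mask, kind = "rectangle")
}

#' Grid of square ROI cells
#'
#' Tiles the elastogram box with square cells of side `cell_mm`
#' (`round(cell_mm / mm_per_px)` pixels), anchored at the box's top-left
#' corner. Only complete cells are kept — partial boundary cells are excluded
#' rather than clipped, so all cells have equal area and their statistics are
#' comparable. Labels increase row-major.
#'
#' @param geom An [elastogram_geometry()].
#' @param cell_mm Cell side in mm (default 4).
#' @return A `sweclip_roi` of kind `"grid"` with `cell_id` labels.
#' @export
build_grid <- function(geom, cell_mm = 4) {
  if (!is.numeric(cell_mm) || length(cell_mm) != 1L || cell_mm <= 0) {
    stop("cell_mm must be a single positive number")
  }
  cell_px <- round(cell_mm / geom$mm_per_px)
  if (cell_px < 1) stop("cell_mm is smaller than one pixel")
  H <- rect_height(geom$box); W <- rect_width(geom$box)
  n_rows <- floor(H / cell_px)
  n_cols <- floor(W / cell_px)
  if (n_rows * n_cols == 0) {
    stop(sprintf(paste0(
      "elastogram box (%d x %d px) holds no complete %g mm cell ",
      "(%d px); use a manual rectangle ROI instead"), H, W, cell_mm, cell_px))
  }
  cell_id <- matrix(0L, H, W)
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      cell_id[((i - 1) * cell_px + 1):(i * cell_px),
              ((j - 1) * cell_px + 1):(j * cell_px)] <- (i - 1L) * n_cols + j
    }
  }
  new_roi_mask(cell_id > 0L, cell_id = cell_id, kind = "grid")
}

#' Whole-box rectangle ROI
#'
#' Convenience wrapper selecting the full elastogram box.
#'
#' @param geom An [elastogram_geometry()].
#' @return A `sweclip_roi` of kind `"rectangle"`.
#' @export
build_full_mask <- function(geom) {
  H <- rect_height(geom$box); W <- rect_width(geom$box)
  new_roi_mask(matrix(TRUE, H, W), kind = "rectangle")
}
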