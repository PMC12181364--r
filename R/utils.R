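#' Pixel rectangles
#'
#' Rectangles are stored half-open and zero-based, like array slices:
#' `[row0, row1) x [col0, col1)`. The matching R matrix indices are
#' `(row0 + 1):row1` and `(col0 + 1):col1`. Half-open edges eliminate double
#' counting where two rectangles share a border.
#'
#' @param row0,row1 First (inclusive) and last (exclusive) row, zero-based.
#' @param col0,col1 First (inclusive) and last (exclusive) column, zero-based.
#' @return An object of class `px_rect`.
#' @export
px_rect <- function(row0, row1, col0, col1) {
  for (v in list(row0, row1, col0, col1)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v)) {
      stop("px_rect coordinates must be single non-negative integers")
    }
  }
  if (row1 <= row0 || col1 <= col0) {
    stop("px_rect must have positive height and width (half-open bounds)")
  }
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1)),
            class = "px_rect")
}

#' @export
format.px_rect <- function(x, ...) {
  sprintf("px_rect rows [%d, %d) cols [%d, %d) (%d x %d px)",
          x$row0, x$row1, x$col0, x$col1, rect_height(x), rect_width(x))
}

#' @export
print.px_rect <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname px_rect
#' @param rect A `px_rect`.
#' @export
rect_height <- function(rect) rect$row1 - rect$row0

#' @rdname px_rect
#' @export
rect_width <- function(rect) rect$col1 - rect$col0

# 1-based R indices covered by a rectangle
rect_row_idx <- function(rect) (rect$row0 + 1L):rect$row1
rect_col_idx <- function(rect) (rect$col0 + 1L):rect$col1

rect_inside <- function(rect, nrow, ncol) {
  rect$row0 >= 0L && rect$col0 >= 0L && rect$row1 <= nrow && rect$col1 <= ncol
}

# Round half away from zero (display channels are rendered with this
# convention so round-trip error bounds stay provable; base round() is
# round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-frame seed derived from a clip seed.
frame_seed <- function(seed, frame_index, stream = 0L) {
  (as.numeric(seed) * 7919 + as.numeric(frame_index) * 104729 +
     as.numeric(stream) * 15485863) %% 2147483629
}
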