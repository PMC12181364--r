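round_half_away <- sweclip:::round_half_away

# Small synthetic-clip configuration used across the suite: keeps frames
# modest (140 x 200 px, 80 x 120 px elastogram) so decoding stays fast.
# Colorbar height 81 px and ruler ticks 100 px apart are chosen so the
# fixture's geometry is exactly recoverable.
tiny_config <- function(..., n_frames = 3L) {
  synthetic_clip_config(
    height = 140L, width = 200L,
    box = px_rect(20, 100, 30, 150),
    mm_per_px = 0.1,
    e_max = 100,
    ruler = list(region = px_rect(10, 130, 170, 185), tick_interval_mm = 10),
    colorbar = list(region = px_rect(20, 101, 8, 16)),
    n_frames = n_frames,
    ...)
}

# A plain frame: constant gray with a 1-px ring drawn in `color` around the
# zero-based half-open interior box `rect`.
ring_frame <- function(rect, color = c(240, 130, 40), gray = 60,
                       height = 300L, width = 420L) {
  img <- array(gray, dim = c(height, width, 3L))
  rr <- rect$row0:(rect$row1 + 1L)       # R indices of ring rows/cols
  cc <- rect$col0:(rect$col1 + 1L)
  for (ch in 1:3) {
    img[rr[1], cc, ch] <- color[ch]
    img[rr[length(rr)], cc, ch] <- color[ch]
    img[rr, cc[1], ch] <- color[ch]
    img[rr, cc[length(cc)], ch] <- color[ch]
  }
  frame_image(img, index = 0L)
}

# Build a sweclip_field directly from a values/valid pair (unit-test shim).
make_field <- function(values, valid = !is.na(values), e_max = 100,
                       frame_index = 0L) {
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid,
                 frame_index = frame_index, e_max = e_max),
            class = "sweclip_field")
}

# Geometry helper for ROI tests: a box of the given pixel size.
toy_geometry <- function(h_px, w_px, mm_per_px = 0.1) {
  elastogram_geometry(px_rect(0, h_px, 0, w_px), mm_per_px, mode = "manual")
}
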