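#' Elasticity colormap specification
#'
#' An elastogram colormap is a list of ordered color stops mapping normalized
#' elasticity (0 = softest, 1 = stiffest) to RGB. Display devices superimpose
#' the colored elastogram over the grayscale B-mode image at a fixed opacity
#' (`alpha`, default 0.5), so the colors actually observed on screen are
#' alpha-blends of colormap colors with unknown per-pixel gray levels.
#' Decoding inverts that blend (see [decode_pixel()]).
#'
#' @param positions Numeric vector of stop positions in `[0, 1]`, strictly
#'   increasing, starting at 0 and ending at 1.
#' @param colors Matrix with one RGB row per stop, channels in `[0, 255]`.
#'   The first stop is the lowest-elasticity color (blue on the temperature
#'   scale), the last the highest (red).
#' @param n_lut Number of discrete lookup-table samples used by the decoder
#'   (`>= 32`). Decoded values are quantized to `e_max / (n_lut - 1)`.
#' @param alpha Overlay opacity in `(0, 1]`.
#' @return An object of class `sweclip_colormap`.
#' @seealso [default_colormap()], [sample_colorbar()], [read_colormap_csv()]
#' @export
colormap_spec <- function(positions, colors, n_lut = 256L, alpha = 0.5) {
  positions <- as.numeric(positions)
  colors <- as.matrix(colors)
  if (length(positions) < 2L || nrow(colors) != length(positions) ||
      ncol(colors) != 3L) {
    stop("need >= 2 stops, one RGB row per position")
  }
  if (any(diff(positions) <= 0)) stop("stop positions must be strictly increasing")
  if (abs(positions[1]) > 1e-12 || abs(positions[length(positions)] - 1) > 1e-12) {
    stop("first stop position must be 0 and last must be 1")
  }
  if (anyNA(colors) || min(colors) < 0 || max(colors) > 255) {
    stop("stop colors must lie in [0, 255]")
  }
  if (!is.numeric(n_lut) || length(n_lut) != 1L || n_lut < 32L) {
    stop("n_lut must be a single integer >= 32")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  positions[1] <- 0
  positions[length(positions)] <- 1
  dimnames(colors) <- list(NULL, c("r", "g", "b"))
  structure(list(positions = positions, colors = colors,
                 n_lut = as.integer(n_lut), alpha = alpha),
            class = "sweclip_colormap")
}

#' @export
print.sweclip_colormap <- function(x, ...) {
  cat(sprintf("<sweclip_colormap> %d stops, n_lut = %d, alpha = %g\n",
              length(x$positions), x$n_lut, x$alpha))
  invisible(x)
}

#' Default blue-to-red temperature colormap
#'
#' Six stops blue, cyan, green, yellow, orange, red at uniform positions —
#' the conventional temperature gradient with low elasticity in blue and high
#' in red. Vendors do not publish their exact colormap RGB values, so prefer
#' self-calibration with [sample_colorbar()] from the on-screen color bar
#' when a bar region is available; this default is the fallback and the map
#' used by the synthetic renderer.
#'
#' @inheritParams colormap_spec
#' @return A `sweclip_colormap`.
#' @export
default_colormap <- function(n_lut = 256L, alpha = 0.5) {
  colormap_spec(
    positions = seq(0, 1, length.out = 6L),
    colors = rbind(c(0, 0, 255), c(0, 255, 255), c(0, 255, 0),
                   c(255, 255, 0), c(255, 128, 0), c(255, 0, 0)),
    n_lut = n_lut, alpha = alpha
  )
}

#' Read a colormap stop file
#'
#' Plain-text CSV with header `position,r,g,b`, positions in `[0, 1]`.
#'
#' @param path File path.
#' @inheritParams colormap_spec
#' @return A `sweclip_colormap`.
#' @export
read_colormap_csv <- function(path, n_lut = 256L, alpha = 0.5) {
  df <- utils::read.csv(path)
  need <- c("position", "r", "g", "b")
  if (!all(need %in% names(df))) {
    stop("colormap file must have columns position,r,g,b")
  }
  colormap_spec(df$position, as.matrix(df[, c("r", "g", "b")]),
                n_lut = n_lut, alpha = alpha)
}

#' Elasticity scale
#'
#' The maximum of the elasticity color bar displayed on screen, in kPa. It is
#' user-supplied per clip and must match the range the device displayed when
#' the clip was exported; all decoded values are proportional to it.
#'
#' @param e_max Maximum of the color scale in kPa, `> 0`.
#' @return An object of class `sweclip_scale`.
#' @export
elasticity_scale <- function(e_max) {
  if (!is.numeric(e_max) || length(e_max) != 1L || !is.finite(e_max) ||
      e_max <= 0) {
    stop("e_max must be a single positive number (kPa)")
  }
  structure(list(e_max = as.numeric(e_max)), class = "sweclip_scale")
}

as_scale <- function(scale) {
  if (inherits(scale, "sweclip_scale")) scale else elasticity_scale(scale)
}

#' Discretized colormap lookup table
#'
#' Piecewise-linear interpolation of the stops at `n_lut` uniform positions.
#'
#' @param cmap A `sweclip_colormap`.
#' @return `n_lut x 3` matrix of real-valued channels in `[0, 255]`.
#' @export
colormap_lut <- function(cmap) {
  p <- seq(0, 1, length.out = cmap$n_lut)
  vapply(1:3, function(ch) {
    stats::approx(cmap$positions, cmap$colors[, ch], xout = p)$y
  }, numeric(cmap$n_lut))
}

#' Map elasticity values to colormap colors
#'
#' Forward model of the display: `v / e_max` is clamped to `[0, 1]` and the
#' RGB color obtained by piecewise-linear interpolation between the enclosing
#' stops. Channels are returned real-valued (before any rounding).
#'
#' @param v Elasticity values in kPa, `>= 0`.
#' @param scale An [elasticity_scale()] (or a bare `e_max` in kPa).
#' @param cmap A `sweclip_colormap`.
#' @return `length(v) x 3` matrix of real-valued channels.
#' @export
value_to_rgb <- function(v, scale, cmap = default_colormap()) {
  scale <- as_scale(scale)
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop("v must be finite numeric")
  }
  if (any(v < 0)) stop("v must be >= 0")
  t <- clamp(v / scale$e_max, 0, 1)
  out <- vapply(1:3, function(ch) {
    stats::approx(cmap$positions, cmap$colors[, ch], xout = t)$y
  }, numeric(length(t)))
  if (!is.matrix(out)) out <- matrix(out, ncol = 3L)
  colnames(out) <- c("r", "g", "b")
  out
}

#' Alpha-blend a color over a gray background
#'
#' Each channel becomes `alpha * color + (1 - alpha) * gray` — the screen
#' compositing model for an elastogram displayed at opacity `alpha` over the
#' grayscale B-mode image.
#'
#' @param color RGB triple or `n x 3` matrix, channels in `[0, 255]`.
#' @param gray Scalar or length-`n` vector of 8-bit gray levels.
#' @param alpha Blend fraction in `(0, 1]`.
#' @return Real-valued blended channels, same shape as `color`.
#' @export
blend_over_gray <- function(color, gray, alpha = 0.5) {
  if (is.null(dim(color))) color <- matrix(as.numeric(color), ncol = 3L)
  if (anyNA(color) || min(color) < 0 || max(color) > 255) {
    stop("color channels must lie in [0, 255]")
  }
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255) {
    stop("gray must lie in [0, 255]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  out <- alpha * color + (1 - alpha) * gray
  colnames(out) <- c("r", "g", "b")
  out
}

# Vectorized decoding core.
#
# For channel vectors (r, g, b), finds for every pixel the nearest neighbour
# over the achievable blended set {alpha * lut[k] + (1 - alpha) * g : all LUT
# indices k, gray levels g on a uniform grid}. Written as a loop over k with
# the optimal grid gray obtained in closed form: the squared distance is
# convex in g, so the grid minimizer is the grid point nearest the continuous
# minimizer g* = mean(p - alpha * lut[k]) / (1 - alpha) (clamped). This is
# exactly the brute-force minimum over (k, g) pairs, ties broken toward the
# lower LUT index.
#
# Returns list(class = character, value = numeric kPa (NA when not colored),
#              dist = min distance, k = best LUT index).
decode_rgb_core <- function(r, g, b, scale, cmap,
                            chroma_tol = 8, gamut_tol = 12,
                            gray_step = 4, out_of_gamut = c("absent", "nearest")) {
  scale <- as_scale(scale)
  out_of_gamut <- match.arg(out_of_gamut)
  lut <- colormap_lut(cmap)
  a <- cmap$alpha
  n <- length(r)
  gmax <- 255 - (255 %% gray_step)  # top of the gray grid

  best_d2 <- rep(Inf, n)
  best_k <- rep(NA_integer_, n)
  for (k in seq_len(cmap$n_lut)) {
    ur <- r - a * lut[k, 1]
    ug <- g - a * lut[k, 2]
    ub <- b - a * lut[k, 3]
    if (a < 1) {
      gb <- (ur + ug + ub) / (3 * (1 - a))
      gs <- clamp(round(gb / gray_step) * gray_step, 0, gmax)
      w <- (1 - a) * gs
      d2 <- (ur - w)^2 + (ug - w)^2 + (ub - w)^2
    } else {
      d2 <- ur^2 + ug^2 + ub^2
    }
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_k[upd] <- k
    }
  }

  chroma <- pmax(r, g, b) - pmin(r, g, b)
  dist <- sqrt(best_d2)
  cls <- rep("colored", n)
  cls[dist > gamut_tol] <- "out_of_gamut"
  cls[chroma <= chroma_tol] <- "grayscale"  # classification precedes decoding

  value <- scale$e_max * (best_k - 1) / (cmap$n_lut - 1)
  value[cls == "grayscale"] <- NA_real_
  if (out_of_gamut == "absent") value[cls == "out_of_gamut"] <- NA_real_
  list(class = cls, value = value, dist = dist, k = best_k)
}

check_rgb_triples <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L)
  if (ncol(p) != 3L || anyNA(p) || min(p) < 0 || max(p) > 255) {
    stop("pixels must be RGB triples with channels in [0, 255]")
  }
  p
}

#' Classify a pixel as colored, grayscale, or out of gamut
#'
#' A pixel carries an elasticity value only if it is colored: achromatic
#' pixels (channel range `<= chroma_tol`) are B-mode background, and chromatic
#' pixels farther than `gamut_tol` from every achievable blended colormap
#' color (text, frame lines, UI elements) are out of gamut.
#'
#' @param p RGB triple or `n x 3` matrix.
#' @param cmap A `sweclip_colormap`.
#' @param chroma_tol Maximum channel range (8-bit units) still counted as
#'   grayscale. Default 8 tolerates rounding plus light compression noise.
#' @param gamut_tol Maximum distance (8-bit units) to the nearest achievable
#'   blended colormap color. Default 12.
#' @param gray_step Gray-grid step of the achievable blended set.
#' @return Character vector with values `"colored"`, `"grayscale"`,
#'   `"out_of_gamut"`.
#' @export
classify_pixel <- function(p, cmap = default_colormap(), chroma_tol = 8,
                           gamut_tol = 12, gray_step = 4) {
  p <- check_rgb_triples(p)
  decode_rgb_core(p[, 1], p[, 2], p[, 3], elasticity_scale(1), cmap,
                  chroma_tol, gamut_tol, gray_step)$class
}

#' Decode observed pixels back to Young's modulus
#'
#' Assigns each colored pixel the elasticity value of the nearest achievable
#' blended colormap color: the decoded value is `e_max * k / (n_lut - 1)`
#' where `k` indexes the nearest-neighbour match over all (LUT color, gray
#' level) alpha-blends. Grayscale pixels decode to `NA` (they carry no
#' elasticity value); out-of-gamut pixels decode to `NA` by default or to the
#' nearest colormap value when `out_of_gamut = "nearest"`.
#'
#' @inheritParams classify_pixel
#' @param scale An [elasticity_scale()] (or bare `e_max` in kPa).
#' @param out_of_gamut `"absent"` (default) or `"nearest"`.
#' @return Numeric vector of kPa values, `NA` where absent.
#' @export
decode_pixel <- function(p, scale, cmap = default_colormap(), chroma_tol = 8,
                         gamut_tol = 12, gray_step = 4,
                         out_of_gamut = c("absent", "nearest")) {
  p <- check_rgb_triples(p)
  decode_rgb_core(p[, 1], p[, 2], p[, 3], scale, cmap, chroma_tol, gamut_tol,
                  gray_step, out_of_gamut)$value
}

#' Recover the colormap from the on-screen color bar
#'
#' The displayed color bar is the only in-image source of the device's true
#' colormap. Samples `n_stops` evenly spaced rows of the bar (median color
#' across the bar's width per row, robust to edge pixels) and returns a
#' colormap whose stops sit at uniform positions in `[0, 1]`.
#'
#' @param frame A [frame_image()].
#' @param bar_box `px_rect` of the bar inside the frame.
#' @param n_stops Number of stops to sample (`>= 2`).
#' @param top_is_max If `TRUE` (default convention) the top bar row shows
#'   `e_max` and the bottom row 0.
#' @inheritParams colormap_spec
#' @return A `sweclip_colormap`.
#' @export
sample_colorbar <- function(frame, bar_box, n_stops = 6L, top_is_max = TRUE,
                            n_lut = 256L, alpha = 0.5) {
  px <- crop_pixels(frame, bar_box)
  h <- dim(px)[1]
  if (h < 2L || n_stops < 2L) stop("color bar must span >= 2 rows and stops")
  pos <- seq(0, 1, length.out = n_stops)
  rows <- round(if (top_is_max) (1 - pos) * (h - 1) else pos * (h - 1)) + 1L
  cols <- t(vapply(rows, function(rw) {
    apply(px[rw, , , drop = FALSE], 3, stats::median)
  }, numeric(3)))
  if (nrow(unique(round(cols))) < 2L) {
    stop("degenerate color bar: fewer than 2 distinct sampled colors")
  }
  colormap_spec(pos, cols, n_lut = n_lut, alpha = alpha)
}
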