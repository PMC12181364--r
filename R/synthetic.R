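#' Synthetic clip configuration
#'
#' Describes a fully synthetic SWE screen: grayscale B-mode background, an
#' elasticity field alpha-blended over it inside the elastogram box, a
#' colored frame line around the box, a tick-marked measurement bar, and an
#' opaque color bar. Everything every pipeline stage relies on is rendered
#' from a known ground truth, so detection, scale calibration, decoding and
#' statistics can be validated without any patient data.
#'
#' Defaults emulate a muscle clip exported with an individually adjusted
#' elasticity range: `e_max = 100` kPa (ranges are tuned per clip so the
#' elastogram spans a wide color range rather than sitting at the 300 kPa
#' device maximum), a smoothly varying field around 40 kPa, mild per-frame
#' fluctuation, and patchy signal dropout.
#'
#' @param height,width Frame size in px.
#' @param box Elastogram interior `px_rect`.
#' @param mm_per_px Physical scale, mm per pixel.
#' @param e_max Color-scale maximum in kPa.
#' @param field List: `model` (`"constant"`, `"gradient"`, `"smooth"`),
#'   `base` (kPa), `amplitude` (kPa), `corr_px` (spatial correlation length,
#'   px, smooth model), `jitter_sd` (per-frame temporal jitter SD, kPa).
#' @param dropout Fraction of elastogram pixels without signal (shown as bare
#'   background), in `[0, 1)`.
#' @param background List: `mean`, `sd` of the clipped Gaussian gray noise
#'   standing in for B-mode texture.
#' @param cmap A `sweclip_colormap` (its `alpha` is the blend opacity).
#' @param frame_line List: `color` (RGB triple or `"white"`), `width` (px).
#' @param ruler List: `region` (`px_rect`), `tick_interval_mm`.
#' @param colorbar List: `region` (`px_rect`).
#' @param n_frames Number of frames.
#' @param seed Integer seed; output is bit-reproducible given the config.
#' @return Object of class `sweclip_synth_config`.
#' @export
synthetic_clip_config <- function(
    height = 360L, width = 480L,
    box = px_rect(40, 240, 70, 370),
    mm_per_px = 0.1,
    e_max = 100,
    field = list(),
    dropout = 0.1,
    background = list(),
    cmap = default_colormap(),
    frame_line = list(),
    ruler = list(),
    colorbar = list(),
    n_frames = 5L,
    seed = 1L) {
  field <- utils::modifyList(
    list(model = "smooth", base = 40, amplitude = 15, corr_px = 25,
         jitter_sd = 2), field)
  background <- utils::modifyList(list(mean = 60, sd = 25), background)
  frame_line <- utils::modifyList(
    list(color = c(240, 130, 40), width = 1L), frame_line)
  if (identical(frame_line$color, "white")) frame_line$color <- c(255, 255, 255)
  if (identical(frame_line$color, "orange")) frame_line$color <- c(240, 130, 40)
  ruler <- utils::modifyList(
    list(region = px_rect(20, 340, 440, 452), tick_interval_mm = 10), ruler)
  colorbar <- utils::modifyList(list(region = px_rect(40, 241, 16, 32)),
                                colorbar)
  if (!rect_inside(box, height, width)) stop("box must lie inside the frame")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (!field$model %in% c("constant", "gradient", "smooth")) {
    stop("field$model must be constant, gradient or smooth")
  }
  if (n_frames < 1L) stop("n_frames must be >= 1")
  structure(list(height = as.integer(height), width = as.integer(width),
                 box = box, mm_per_px = mm_per_px, e_max = e_max,
                 field = field, dropout = dropout, background = background,
                 cmap = cmap, frame_line = frame_line, ruler = ruler,
                 colorbar = colorbar, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "sweclip_synth_config")
}

#' Ground-truth elasticity field for one frame
#'
#' Deterministic given `(seed, frame_index)`. The smooth model filters white
#' noise with a Gaussian kernel of the configured correlation length and
#' rescales it to the requested base/amplitude; temporal jitter adds one
#' scalar offset per frame. Values are clipped to `[0, e_max]`; the dropout
#' mask marks pixels that will be rendered as bare background.
#'
#' @param config A [synthetic_clip_config()].
#' @param frame_index Zero-based frame number.
#' @return List with `values` (kPa matrix, clipped), `valid` (logical
#'   matrix, `FALSE` = dropout), `frame_index`.
#' @export
generate_field <- function(config, frame_index = 0L) {
  H <- rect_height(config$box); W <- rect_width(config$box)
  f <- config$field
  # the spatial pattern belongs to the clip (seeded by the clip seed only);
  # temporal jitter and dropout are per-frame
  values <- with_seed(frame_seed(config$seed, 0L, stream = 1L), {
    switch(f$model,
      constant = matrix(f$base, H, W),
      gradient = matrix(rep(seq(f$base, f$base + f$amplitude, length.out = W),
                            each = H), H, W),
      smooth = {
        z <- matrix(stats::rnorm(H * W), H, W)
        zs <- EBImage::gblur(z, sigma = f$corr_px / 2)
        zs <- (zs - mean(zs)) / stats::sd(as.numeric(zs))
        f$base + f$amplitude * zs
      })
  })
  with_seed(frame_seed(config$seed, frame_index, stream = 3L), {
    if (f$jitter_sd > 0) values <- values + stats::rnorm(1L, 0, f$jitter_sd)
    values <- clamp(values, 0, config$e_max)
    valid <- matrix(stats::runif(H * W) >= config$dropout, H, W)
    list(values = values, valid = valid, frame_index = as.integer(frame_index))
  })
}

# deterministic per-frame background (full frame)
synth_background <- function(config, frame_index) {
  with_seed(frame_seed(config$seed, frame_index, stream = 2L), {
    matrix(clamp(round(stats::rnorm(config$height * config$width,
                                    config$background$mean,
                                    config$background$sd)), 0, 255),
           config$height, config$width)
  })
}

#' Render one synthetic frame
#'
#' Forward model of the display: inside the elastogram box, valid pixels show
#' the rounded (half away from zero) alpha-blend of the colormap color of the
#' ground-truth value over the gray background; dropout pixels show bare
#' background. The frame line, ruler ticks and color bar are drawn at their
#' configured positions; the color bar is drawn opaque with its top row at
#' `e_max`.
#'
#' @param field Output of [generate_field()].
#' @param config The [synthetic_clip_config()].
#' @return A [frame_image()].
#' @export
render_frame <- function(field, config) {
  H <- config$height; W <- config$width
  bg <- synth_background(config, field$frame_index)
  img <- array(bg, dim = c(H, W, 3L))

  # elastogram overlay
  ri <- rect_row_idx(config$box); ci <- rect_col_idx(config$box)
  cols <- value_to_rgb(as.numeric(field$values), config$e_max, config$cmap)
  a <- config$cmap$alpha
  bgbox <- bg[ri, ci]
  for (ch in 1:3) {
    chan <- matrix(cols[, ch], nrow(field$values), ncol(field$values))
    blended <- round_half_away(a * chan + (1 - a) * bgbox)
    sub <- img[ri, ci, ch]
    sub[field$valid] <- blended[field$valid]
    img[ri, ci, ch] <- sub
  }

  # frame line ring just outside the interior box
  lw <- config$frame_line$width
  lc <- config$frame_line$color
  b <- config$box
  rr <- (b$row0 - lw + 1L):(b$row1 + lw)   # R indices incl. the ring
  cc <- (b$col0 - lw + 1L):(b$col1 + lw)
  if (min(rr) < 1L || max(rr) > H || min(cc) < 1L || max(cc) > W) {
    stop("frame line does not fit inside the frame")
  }
  for (ch in 1:3) {
    img[rr[1:lw], cc, ch] <- lc[ch]
    img[rr[(length(rr) - lw + 1L):length(rr)], cc, ch] <- lc[ch]
    img[rr, cc[1:lw], ch] <- lc[ch]
    img[rr, cc[(length(cc) - lw + 1L):length(cc)], ch] <- lc[ch]
  }

  # measurement bar: dark band with bright ticks every tick_interval_mm
  rg <- config$ruler$region
  rri <- rect_row_idx(rg); rci <- rect_col_idx(rg)
  img[rri, rci, ] <- 20L
  tick_px <- config$ruler$tick_interval_mm / config$mm_per_px
  tick_rows <- seq(rg$row0, rg$row1 - 1L, by = tick_px)
  for (tr in round(tick_rows)) img[tr + 1L, rci, ] <- 255L
  # color bar, opaque, top = e_max
  cb <- config$colorbar$region
  nh <- rect_height(cb)
  vals <- config$e_max * (nh - seq_len(nh)) / (nh - 1)
  bar <- round_half_away(value_to_rgb(vals, config$e_max, config$cmap))
  for (ch in 1:3) {
    img[rect_row_idx(cb), rect_col_idx(cb), ch] <-
      matrix(bar[, ch], nh, rect_width(cb))
  }
  frame_image(img, index = field$frame_index)
}

#' Generate a full synthetic clip with ground truth
#'
#' @param config A [synthetic_clip_config()].
#' @return List with `frames` (list of [frame_image()]), `fields` (ground
#'   truth per frame), `truth` (per-frame data frame: `frame_index`,
#'   `true_mean` over valid clipped values, `true_fill_pct`), `config`.
#' @export
generate_clip <- function(config) {
  fields <- lapply(seq_len(config$n_frames) - 1L,
                   function(i) generate_field(config, i))
  frames <- lapply(fields, render_frame, config = config)
  truth <- do.call(rbind, lapply(fields, function(f) {
    data.frame(frame_index = f$frame_index,
               true_mean = mean(f$values[f$valid]),
               true_fill_pct = 100 * mean(f$valid))
  }))
  list(frames = frames, fields = fields, truth = truth, config = config)
}

#' Write a clip to disk
#'
#' `"png"` writes a directory of zero-padded per-frame PNGs (the lossless
#' fixture dialect); `"dicom"` writes one uncompressed RGB multi-frame DICOM
#' file. A ground-truth CSV is written alongside when truth is supplied.
#'
#' @param frames List of [frame_image()]s.
#' @param path Output directory (png) or file (dicom).
#' @param format `"png"` or `"dicom"`.
#' @param truth Optional ground-truth data frame.
#' @return `path`, invisibly.
#' @export
write_clip <- function(frames, path, format = c("png", "dicom"),
                       truth = NULL) {
  format <- match.arg(format)
  if (length(frames) == 0L) stop("cannot write a clip with 0 frames")
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frames)) {
      png::writePNG(frames[[i]]$pixels / 255,
                    file.path(path, sprintf("frame_%04d.png", i - 1L)))
    }
    if (!is.null(truth)) {
      utils::write.csv(truth, file.path(path, "ground_truth.csv"),
                       row.names = FALSE)
    }
  } else {
    write_dicom_rgb(frames, path)
    if (!is.null(truth)) {
      utils::write.csv(truth, paste0(tools::file_path_sans_ext(path),
                                     "_ground_truth.csv"), row.names = FALSE)
    }
  }
  invisible(path)
}
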