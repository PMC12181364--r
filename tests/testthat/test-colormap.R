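two_stop <- colormap_spec(c(0, 1), rbind(c(0, 0, 255), c(255, 0, 0)))

test_that("value_to_rgb interpolates between stops and clamps at the ends", {
  cmap <- default_colormap()
  expect_equal(as.numeric(value_to_rgb(0, 300, cmap)), c(0, 0, 255))
  expect_equal(as.numeric(value_to_rgb(300, 300, cmap)), c(255, 0, 0))
  expect_equal(as.numeric(value_to_rgb(500, 300, cmap)), c(255, 0, 0))
  expect_equal(as.numeric(value_to_rgb(150, 300, two_stop)),
               c(127.5, 0, 127.5))
  expect_error(value_to_rgb(NaN, 300, cmap), "finite")
  expect_error(value_to_rgb(-1, 300, cmap), ">= 0")
})

test_that("blend_over_gray is the per-channel convex combination", {
  expect_equal(as.numeric(blend_over_gray(c(255, 0, 0), 0, 0.5)),
               c(127.5, 0, 0))
  expect_equal(as.numeric(blend_over_gray(c(255, 0, 0), 255, 0.5)),
               c(255, 127.5, 127.5))
  # achromatic closure: equal channels stay equal under any blend
  for (g in c(0, 85, 200)) {
    for (a in c(0.3, 0.5, 1)) {
      out <- as.numeric(blend_over_gray(c(g, g, g), 137, a))
      expect_true(all(out == out[1]))
    }
  }
  expect_error(blend_over_gray(c(300, 0, 0), 0, 0.5), "\\[0, 255\\]")
  expect_error(blend_over_gray(c(255, 0, 0), 0, 0), "\\(0, 1\\]")
})

test_that("pixel classification separates colored, grayscale and out-of-gamut", {
  expect_equal(classify_pixel(c(128, 128, 128)), "grayscale")
  # forward-render with the module's own blend, then classify
  p <- round_half_away(blend_over_gray(value_to_rgb(150, 300, two_stop), 40, 0.5))
  expect_equal(as.numeric(p), c(84, 20, 84))
  expect_equal(classify_pixel(p, two_stop), "colored")
  expect_equal(classify_pixel(c(0, 255, 0), two_stop, gamut_tol = 10),
               "out_of_gamut")
})

test_that("out-of-gamut call matches brute-force enumeration of the blended set", {
  # minimum distance of pure green to every (LUT sample, gray level) blend
  lut <- colormap_lut(two_stop)
  grays <- seq(0, 252, by = 4)
  p <- c(0, 255, 0)
  dmin <- min(vapply(seq_len(nrow(lut)), function(k) {
    min(sqrt(colSums((0.5 * lut[k, ] + 0.5 * rep(grays, each = 3) -
                        p)^2 |> matrix(nrow = 3))))
  }, numeric(1)))
  expect_gt(dmin, 10)
  expect_equal(classify_pixel(p, two_stop, gamut_tol = ceiling(dmin) + 1),
               "colored")
})

test_that("decode_pixel round-trips rendered values and skips gray pixels", {
  e_max <- 300
  p <- round_half_away(blend_over_gray(value_to_rgb(150, e_max), 40, 0.5))
  tol <- e_max / 255 + 2 * e_max / 255  # quantization + rounding slack
  expect_lt(abs(decode_pixel(p, e_max) - 150), tol)
  expect_true(is.na(decode_pixel(c(60, 60, 60), e_max)))
  p_top <- round_half_away(blend_over_gray(value_to_rgb(e_max, e_max), 0, 0.5))
  expect_equal(decode_pixel(p_top, e_max), e_max)
})

test_that("fast decoder equals literal brute force over (LUT, gray) pairs", {
  cmap <- default_colormap()
  e_max <- 300
  lut <- colormap_lut(cmap)
  grays <- seq(0, 252, by = 4)
  set.seed(42)
  vs <- runif(40, 0, e_max)
  gs <- sample(0:255, 40, replace = TRUE)
  px <- round_half_away(blend_over_gray(value_to_rgb(vs, e_max, cmap), gs, 0.5))
  fast <- decode_pixel(px, e_max, cmap)
  brute <- vapply(seq_len(nrow(px)), function(i) {
    best <- Inf; bk <- NA_integer_
    for (k in seq_len(nrow(lut))) {
      d2 <- min(colSums((0.5 * lut[k, ] + 0.5 * rep(grays, each = 3) -
                           as.numeric(px[i, ]))^2 |> matrix(nrow = 3)))
      if (d2 < best - 1e-12) { best <- d2; bk <- k }
    }
    e_max * (bk - 1) / (nrow(lut) - 1)
  }, numeric(1))
  expect_equal(fast, brute)
})

test_that("unblended LUT colors decode monotonically at full opacity", {
  cmap <- default_colormap(alpha = 1)
  lut <- round_half_away(colormap_lut(cmap))
  dec <- decode_pixel(lut, 100, cmap)
  expect_false(anyNA(dec))
  expect_true(all(diff(dec) > 0))
})

test_that("achromatic pixels never decode to a value", {
  px <- cbind(0:255, 0:255, 0:255)
  expect_true(all(is.na(decode_pixel(px, 100))))
  # classification precedes decoding even with a huge gamut tolerance
  expect_true(all(is.na(decode_pixel(px, 100, gamut_tol = 1e6))))
})

test_that("sample_colorbar recovers the rendered colormap", {
  cfg <- tiny_config()
  frame <- render_frame(generate_field(cfg, 0L), cfg)
  rec <- sample_colorbar(frame, cfg$colorbar$region, n_stops = 6L)
  expect_equal(rec$positions, seq(0, 1, length.out = 6))
  expect_true(max(abs(rec$colors - default_colormap()$colors)) <= 2)
  rec5 <- sample_colorbar(frame, cfg$colorbar$region, n_stops = 5L)
  expect_equal(rec5$positions, c(0, 0.25, 0.5, 0.75, 1))
  gray_frame <- frame_image(array(77, c(64, 64, 3)))
  expect_error(sample_colorbar(gray_frame, px_rect(4, 60, 10, 20)),
               "degenerate")
})

test_that("colormap stop files round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(position = default_colormap()$positions,
                   default_colormap()$colors)
  write.csv(df, path, row.names = FALSE)
  cm <- read_colormap_csv(path)
  expect_equal(cm$colors, default_colormap()$colors)
  expect_error(colormap_spec(c(0, 0.5), rbind(c(0, 0, 255), c(255, 0, 0))),
               "last must be 1")
  expect_error(colormap_spec(c(0, 0, 1), rbind(1, 1, 1) %*% t(c(1, 1, 1))),
               "strictly increasing")
})
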