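test_that("ground-truth fields honor the field model", {
  cfg <- tiny_config(field = list(model = "constant", base = 50, jitter_sd = 0),
                     dropout = 0)
  f <- generate_field(cfg, 0L)
  expect_true(all(f$values == 50))
  expect_true(all(f$valid))

  # temporal jitter 0 gives identical fields across frames
  cfg2 <- tiny_config(field = list(model = "smooth", base = 40, amplitude = 10,
                                   corr_px = 15, jitter_sd = 0), dropout = 0)
  expect_equal(generate_field(cfg2, 0L)$values, generate_field(cfg2, 1L)$values)
  # with jitter the frames differ by a scalar offset
  cfg3 <- tiny_config(field = list(model = "smooth", base = 40, amplitude = 10,
                                   corr_px = 15, jitter_sd = 3), dropout = 0)
  d <- generate_field(cfg3, 0L)$values - generate_field(cfg3, 1L)$values
  expect_lt(diff(range(d)), 1e-9)

  # gradient spans base .. base + amplitude across columns
  cfg4 <- tiny_config(field = list(model = "gradient", base = 20,
                                   amplitude = 30, jitter_sd = 0))
  g <- generate_field(cfg4, 0L)
  expect_equal(unique(g$values[, 1]), 20)
  expect_equal(unique(g$values[, ncol(g$values)]), 50)
})

test_that("dropout marks the configured fraction of pixels invalid", {
  cfg <- synthetic_clip_config(box = px_rect(40, 240, 70, 370), dropout = 0.3,
                               seed = 7)
  f <- generate_field(cfg, 0L)   # 300 x 200 box
  expect_lt(abs(mean(!f$valid) - 0.30), 0.01)
})

test_that("generation is deterministic given (seed, frame_index)", {
  cfg <- tiny_config(seed = 99L)
  expect_equal(generate_field(cfg, 3L), generate_field(cfg, 3L))
  expect_equal(render_frame(generate_field(cfg, 2L), cfg),
               render_frame(generate_field(cfg, 2L), cfg))
})

test_that("alpha = 1 renders unblended colormap colors inside the box", {
  cfg <- tiny_config(cmap = default_colormap(alpha = 1),
                     field = list(model = "constant", base = 50, jitter_sd = 0),
                     dropout = 0)
  frame <- render_frame(generate_field(cfg, 0L), cfg)
  expected <- round_half_away(value_to_rgb(50, cfg$e_max, cfg$cmap))
  px <- sweclip:::crop_pixels(frame, cfg$box)
  for (ch in 1:3) expect_true(all(px[, , ch] == expected[ch]))
})

test_that("written clips are bit-reproducible and lossless", {
  cfg <- tiny_config(n_frames = 2L)
  clip <- generate_clip(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_clip(clip$frames, file.path(d1, "clip"), "png", truth = clip$truth)
  write_clip(clip$frames, file.path(d2, "clip"), "png", truth = clip$truth)
  f1 <- list.files(file.path(d1, "clip"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "clip"), full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(tools::md5sum(f1), tools::md5sum(f2),
               ignore_attr = TRUE)

  back <- read_clip(file.path(d1, "clip"))
  expect_equal(length(back), 2L)
  for (i in 1:2) expect_equal(back[[i]]$pixels, clip$frames[[i]]$pixels)

  expect_error(write_clip(list(), file.path(d1, "x"), "png"), "0 frames")
})

test_that("DICOM multi-frame round trip is pixel-identical", {
  cfg <- tiny_config(n_frames = 3L)
  clip <- generate_clip(cfg)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_clip(clip$frames, path, "dicom")
  back <- read_dicom_rgb(path)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$pixels, clip$frames[[i]]$pixels)
    expect_equal(back[[i]]$index, i - 1L)
  }
})

test_that("full pipeline recovers ground truth per field model and seed", {
  for (model in c("constant", "gradient", "smooth")) {
    for (seed in 1:3) {
      cfg <- tiny_config(
        seed = seed, n_frames = 2L, dropout = 0.15,
        field = list(model = model, base = 45, amplitude = 20, corr_px = 15,
                     jitter_sd = 2))
      clip <- generate_clip(cfg)
      geom <- detect_geometry(clip$frames[[1]], cfg$ruler$region,
                              tick_interval_mm = cfg$ruler$tick_interval_mm)
      res <- analyze_clip(clip$frames, geom, build_full_mask(geom),
                          cfg$cmap, cfg$e_max)
      tol <- cfg$e_max / 255 + 0.005 * cfg$e_max
      expect_lt(abs(res$summary$means$mean - mean(clip$truth$true_mean)), tol)
      expect_lt(abs(res$summary$means$fill_pct - 85), 2)
    }
  }
})
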