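test_that("the per-frame statistic vector follows the stated conventions", {
  vals <- matrix(NA_real_, 2, 2)
  vals[] <- c(10, 20, 30, 40)
  field <- make_field(vals, e_max = 100)
  roi <- sweclip:::new_roi_mask(matrix(TRUE, 2, 2), kind = "rectangle")
  st <- frame_stats(field, roi, 100)
  expect_equal(st$n_roi_px, 4L)
  expect_equal(st$n_valid, 4L)
  expect_equal(st$fill_pct, 100)
  expect_equal(st$mean, 25)
  expect_equal(st$median, 25)
  expect_equal(st$sd, sqrt(sum((c(10, 20, 30, 40) - 25)^2) / 3))
  expect_equal(round(st$sd, 3), 12.910)
  expect_equal(st$iqr, 32.5 - 17.5)  # linear-interpolation quartiles
  expect_equal(st$max, 40)
  expect_equal(st$n_top, 0L)
})

test_that("top-of-scale counting uses > 0.98 * e_max", {
  field <- make_field(matrix(c(99, 99), 1, 2), e_max = 100)
  roi <- sweclip:::new_roi_mask(matrix(TRUE, 1, 2), kind = "rectangle")
  st <- frame_stats(field, roi, 100)
  expect_equal(st$n_top, 2L)
  expect_equal(st$pct_top, 100)
  # 98 exactly is not "exceeding"
  field2 <- make_field(matrix(c(98, 99), 1, 2), e_max = 100)
  expect_equal(frame_stats(field2, roi, 100)$n_top, 1L)
})

test_that("an all-gray ROI flags value statistics as missing", {
  field <- make_field(matrix(NA_real_, 3, 3), e_max = 100)
  roi <- sweclip:::new_roi_mask(matrix(TRUE, 3, 3), kind = "rectangle")
  st <- frame_stats(field, roi, 100)
  expect_equal(st$fill_pct, 0)
  expect_true(is.na(st$mean) && is.na(st$median) && is.na(st$sd))
})

test_that("clip summaries average over frames with valid pixels only", {
  mk <- function(vals, idx) {
    v <- matrix(vals, 2, 2)
    frame_stats(make_field(v, e_max = 100, frame_index = idx),
                sweclip:::new_roi_mask(matrix(TRUE, 2, 2), kind = "rectangle"),
                100)
  }
  s30 <- mk(c(30, 30, 30, 30), 0)
  s_missing <- mk(rep(NA_real_, 4), 1)
  s50 <- mk(c(50, 50, 50, 50), 2)
  sm <- summarize_clip(list(s30, s_missing, s50))
  expect_equal(sm$n_frames_total, 3L)
  expect_equal(sm$n_frames_used, 2L)
  expect_equal(sm$means$mean, 40)
  expect_equal(summarize_clip(list(s30))$means$mean, 30)
  expect_equal(summarize_clip(list(s30, mk(c(40, 40, 40, 40), 1)))$means$mean,
               35)
  all_empty <- summarize_clip(list(s_missing))
  expect_equal(all_empty$n_frames_used, 0L)
  expect_true(is.na(all_empty$means$mean))
})

test_that("decode_frame recovers fill fraction and handles bare B-mode", {
  cfg <- tiny_config(dropout = 0.3,
                     field = list(model = "constant", base = 50, jitter_sd = 0))
  field_true <- generate_field(cfg, 0L)
  frame <- render_frame(field_true, cfg)
  geom <- elastogram_geometry(cfg$box, cfg$mm_per_px, "manual")
  dec <- decode_frame(frame, geom, cfg$cmap, cfg$e_max)
  expect_lt(abs(100 * mean(dec$valid) - 70), 2)
  expect_equal(dec$valid, field_true$valid)  # gray holes exactly invalid

  bare <- frame_image(array(60, c(140, 200, 3)))
  dec0 <- decode_frame(bare, geom, cfg$cmap, cfg$e_max)
  expect_false(any(dec0$valid))
})

test_that("analyze_clip recovers a constant field within decode tolerance", {
  cfg <- tiny_config(dropout = 0,
                     field = list(model = "constant", base = 50, jitter_sd = 0),
                     n_frames = 3L)
  clip <- generate_clip(cfg)
  geom <- elastogram_geometry(cfg$box, cfg$mm_per_px, "manual")
  res <- analyze_clip(clip$frames, geom, build_full_mask(geom),
                      cfg$cmap, cfg$e_max)
  tol <- cfg$e_max / 255 + 0.005 * cfg$e_max
  expect_lt(abs(res$summary$means$mean - 50), tol)
  expect_equal(res$summary$means$fill_pct, 100)
  expect_equal(res$per_frame$frame_index, 0:2)
  expect_error(analyze_clip(list(), geom, build_full_mask(geom),
                            cfg$cmap, cfg$e_max), "no frames")
})

test_that("grid-cell-pooled statistics agree with the covering rectangle", {
  cfg <- tiny_config(dropout = 0, n_frames = 1L,
                     field = list(model = "smooth", base = 40, amplitude = 15,
                                  corr_px = 20, jitter_sd = 0))
  clip <- generate_clip(cfg)
  geom <- elastogram_geometry(cfg$box, cfg$mm_per_px, "manual")
  grid <- build_grid(geom, 4)             # 2 x 3 cells of 40 px: 80 x 120 px
  rect <- build_rect_mask(geom, c(0, 0, 12, 8))  # the exact covered area
  expect_equal(grid$mask, rect$mask)
  res_g <- analyze_clip(clip$frames, geom, grid, cfg$cmap, cfg$e_max)
  res_r <- analyze_clip(clip$frames, geom, rect, cfg$cmap, cfg$e_max)
  cells <- res_g$cells
  pooled_mean <- sum(cells$mean * cells$n_valid) / sum(cells$n_valid)
  expect_equal(pooled_mean, res_r$per_frame$mean[1], tolerance = 1e-12)
})

test_that("frame statistics are invariant to analysis order", {
  cfg <- tiny_config(n_frames = 4L)
  clip <- generate_clip(cfg)
  geom <- elastogram_geometry(cfg$box, cfg$mm_per_px, "manual")
  roi <- build_full_mask(geom)
  res <- analyze_clip(clip$frames, geom, roi, cfg$cmap, cfg$e_max)
  res_rev <- analyze_clip(rev(clip$frames), geom, roi, cfg$cmap, cfg$e_max)
  a <- res$per_frame[order(res$per_frame$frame_index), ]
  b <- res_rev$per_frame[order(res_rev$per_frame$frame_index), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_equal(res$summary$means$mean, res_rev$summary$means$mean)
})

test_that("duplicated elastogram frames yield identical statistic rows", {
  cfg <- tiny_config(n_frames = 1L)
  clip <- generate_clip(cfg)
  f2 <- clip$frames[[1]]
  f2$index <- 1L
  geom <- elastogram_geometry(cfg$box, cfg$mm_per_px, "manual")
  res <- analyze_clip(list(clip$frames[[1]], f2), geom,
                      build_full_mask(geom), cfg$cmap, cfg$e_max)
  a <- res$per_frame[1, -1]; b <- res$per_frame[2, -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
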