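#' Read a clip from disk
#'
#' A clip is either a directory of per-frame PNG images (read in lexical
#' order — zero-padded names required) or an uncompressed RGB multi-frame
#' DICOM file. Frames are returned in temporal order as 8-bit RGB
#' [frame_image()]s.
#'
#' @param path Directory (png stack) or file (DICOM).
#' @param format `"auto"` (default: directory -> png, file -> dicom),
#'   `"png"`, or `"dicom"`.
#' @return List of [frame_image()]s, length `>= 1`.
#' @export
read_clip <- function(path, format = c("auto", "png", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) "png" else "dicom"
  }
  if (format == "png") {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("'%s' contains no .png frames", path))
    }
    lapply(seq_along(files), function(i) {
      px <- png::readPNG(files[[i]])
      if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
      if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
      frame_image(round(px * 255), index = i - 1L)
    })
  } else {
    read_dicom_rgb(path)
  }
}

#' Read several clips, tolerating damaged files
#'
#' Batch wrapper around [read_clip()]: unreadable or corrupt inputs produce a
#' named error entry and do not abort the remaining clips.
#'
#' @param paths Character vector of clip paths.
#' @param format Passed to [read_clip()].
#' @return List with `clips` (named list of frame lists), `errors` (named
#'   character vector of failure messages), `n_skipped`.
#' @export
read_clips <- function(paths, format = "auto") {
  clips <- list()
  errors <- character(0)
  for (p in paths) {
    res <- tryCatch(read_clip(p, format), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[p]] <- conditionMessage(res)
    } else {
      clips[[p]] <- res
    }
  }
  list(clips = clips, errors = errors, n_skipped = length(errors))
}

#' Analysis run configuration
#'
#' Bundles every knob of an analysis run. Exactly one ROI mode must be set
#' (`roi_rect_mm` or `grid = TRUE`); manual segmentation requires both
#' `manual_box` and `manual_mm_per_px`.
#'
#' @param input Clip path (directory of PNGs or DICOM file).
#' @param e_max Color-scale maximum in kPa (required).
#' @param colormap `"default"`, a stop-file path, or `"colorbar"` to
#'   self-calibrate from `colorbar_region`.
#' @param colorbar_region `px_rect` of the on-screen color bar (required for
#'   `colormap = "colorbar"`).
#' @param frame_line `"orange"`, `"white"` or `list(rgb=, tol=)` for
#'   automatic segmentation.
#' @param ruler_region `px_rect` of the measurement bar (required for
#'   automatic scale calibration).
#' @param tick_interval_mm Ruler tick spacing in mm.
#' @param manual_box,manual_mm_per_px Manual segmentation fallback.
#' @param roi_rect_mm Rectangle ROI `c(x0, y0, w, h)` in mm, or `NULL`.
#' @param grid Use the square-cell grid ROI.
#' @param cell_mm Grid cell side in mm.
#' @param reference_frame Zero-based frame whose geometry is applied to the
#'   whole clip.
#' @param units `"kpa"`, `"swv"`, or `"both"`.
#' @param rho Tissue density in kg/m3 for SWV conversion.
#' @param out_dir Output directory.
#' @param alpha Overlay opacity of the clip's elastogram.
#' @return Object of class `sweclip_run_config`.
#' @export
run_config <- function(input, e_max,
                       colormap = "default", colorbar_region = NULL,
                       frame_line = "orange", ruler_region = NULL,
                       tick_interval_mm = 10,
                       manual_box = NULL, manual_mm_per_px = NULL,
                       roi_rect_mm = NULL, grid = FALSE, cell_mm = 4,
                       reference_frame = 0L, units = c("kpa", "swv", "both"),
                       rho = 1000, out_dir = ".", alpha = 0.5) {
  units <- match.arg(units)
  if (missing(e_max)) stop("e_max (kPa) is required")
  if (!is.null(roi_rect_mm) && isTRUE(grid)) {
    stop("choose exactly one ROI mode: roi_rect_mm or grid")
  }
  if (xor(is.null(manual_box), is.null(manual_mm_per_px))) {
    stop("manual segmentation requires both manual_box and manual_mm_per_px")
  }
  if (is.null(manual_box) && is.null(ruler_region)) {
    stop("automatic scale calibration requires ruler_region (or go manual)")
  }
  if (identical(colormap, "colorbar") && is.null(colorbar_region)) {
    stop("colormap = 'colorbar' requires colorbar_region")
  }
  structure(list(input = input, e_max = e_max, colormap = colormap,
                 colorbar_region = colorbar_region, frame_line = frame_line,
                 ruler_region = ruler_region,
                 tick_interval_mm = tick_interval_mm,
                 manual_box = manual_box, manual_mm_per_px = manual_mm_per_px,
                 roi_rect_mm = roi_rect_mm, grid = isTRUE(grid),
                 cell_mm = cell_mm, reference_frame = as.integer(reference_frame),
                 units = units, rho = rho, out_dir = out_dir, alpha = alpha),
            class = "sweclip_run_config")
}

add_swv_columns <- function(df, rho) {
  df$mean_swv <- young_to_swv(pmax(df$mean, 0), rho)
  df$median_swv <- young_to_swv(pmax(df$median, 0), rho)
  df$max_swv <- young_to_swv(pmax(df$max, 0), rho)
  df
}

#' Run a full clip analysis
#'
#' Reads the clip, obtains the geometry (automatic from the reference frame,
#' or manual), builds the colormap (default, stop file, or sampled from the
#' on-screen color bar), builds the ROI, analyzes every frame, and writes
#' `per_frame.csv`, `cells.csv` (grid mode), `summary.csv` and `run_log.txt`
#' into the output directory. Young's-modulus columns are in kPa; with
#' `units = "swv"` or `"both"`, companion columns in m/s are added by
#' row-wise conversion, and the clip-level SWV is the across-frame mean of
#' the per-frame converted values.
#'
#' @param config A [run_config()].
#' @return The [analyze_clip()] result, invisibly, with the output paths in
#'   `$paths`.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "sweclip_run_config"))
  frames <- read_clip(config$input)
  log_lines <- c(sprintf("input: %s (%d frames)", config$input,
                         length(frames)))

  ref <- config$reference_frame
  if (ref < 0 || ref >= length(frames)) {
    stop(sprintf("reference_frame %d outside clip (0..%d)", ref,
                 length(frames) - 1L))
  }
  ref_frame <- frames[[ref + 1L]]
  geom <- if (!is.null(config$manual_box)) {
    manual_geometry(config$manual_box, config$manual_mm_per_px,
                    frame = ref_frame)
  } else {
    detect_geometry(ref_frame, config$ruler_region,
                    frame_line = config$frame_line,
                    tick_interval_mm = config$tick_interval_mm)
  }
  log_lines <- c(log_lines,
                 sprintf("geometry (%s, reference frame %d): %s",
                         geom$mode, ref, format(geom$box)),
                 sprintf("scale: %.5f mm/px", geom$mm_per_px))

  cmap <- if (identical(config$colormap, "default")) {
    default_colormap(alpha = config$alpha)
  } else if (identical(config$colormap, "colorbar")) {
    sample_colorbar(ref_frame, config$colorbar_region, alpha = config$alpha)
  } else {
    read_colormap_csv(config$colormap, alpha = config$alpha)
  }

  roi <- if (config$grid) {
    build_grid(geom, config$cell_mm)
  } else if (!is.null(config$roi_rect_mm)) {
    build_rect_mask(geom, config$roi_rect_mm)
  } else {
    build_full_mask(geom)
  }
  log_lines <- c(log_lines, sprintf("roi: %s (%d px)", roi$kind, sum(roi$mask)))

  result <- analyze_clip(frames, geom, roi, cmap, config$e_max)

  per_frame <- result$per_frame
  if (config$units %in% c("swv", "both")) {
    per_frame <- add_swv_columns(per_frame, config$rho)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(per_frame = file.path(config$out_dir, "per_frame.csv"),
                summary = file.path(config$out_dir, "summary.csv"),
                log = file.path(config$out_dir, "run_log.txt"))
  utils::write.csv(per_frame, paths$per_frame, row.names = FALSE)
  if (!is.null(result$cells)) {
    cells <- result$cells
    if (config$units %in% c("swv", "both")) {
      cells <- add_swv_columns(cells, config$rho)
    }
    paths$cells <- file.path(config$out_dir, "cells.csv")
    utils::write.csv(cells, paths$cells, row.names = FALSE)
  }
  sm <- result$summary
  summary_df <- data.frame(n_frames_total = sm$n_frames_total,
                           n_frames_used = sm$n_frames_used,
                           as.data.frame(sm$means))
  names(summary_df)[-(1:2)] <- paste0("mean_", names(sm$means))
  if (config$units %in% c("swv", "both")) {
    # clip-level SWV: mean over frames of the per-frame converted value
    used <- result$per_frame$n_valid > 0
    summary_df$mean_swv <-
      mean(young_to_swv(pmax(result$per_frame$mean[used], 0), config$rho))
  }
  utils::write.csv(summary_df, paths$summary, row.names = FALSE)

  log_lines <- c(log_lines,
                 sprintf("frames used: %d / %d", sm$n_frames_used,
                         sm$n_frames_total),
                 sprintf("mean fill: %.1f %%", sm$means$fill_pct),
                 if (length(result$errors)) {
                   sprintf("frame errors: %s",
                           paste(names(result$errors), collapse = ", "))
                 })
  writeLines(log_lines, paths$log)
  result$paths <- paths
  invisible(result)
}

#' Compare two clip-summary tables
#'
#' Reads two CSV files sharing a clip-identifier column, runs
#' [compare_methods()] on the chosen value column, and writes the agreement
#' report as JSON and CSV plus (optionally) Bland-Altman and correlation
#' plots.
#'
#' @param csv_a,csv_b Paths to the two summary CSVs (method A and B).
#' @param out_dir Output directory.
#' @param id_col Shared clip-identifier column.
#' @param value_col Value column to compare.
#' @param unit Unit label.
#' @param delta,delta_log,alpha Passed to [compare_methods()].
#' @param plots Write PNG plots.
#' @return The `sweclip_comparison`, invisibly, with `$paths`.
#' @export
run_compare <- function(csv_a, csv_b, out_dir = ".", id_col = "clip",
                        value_col = "mean", unit = "", delta = NULL,
                        delta_log = NULL, alpha = 0.05, plots = TRUE) {
  for (p in c(csv_a, csv_b)) {
    if (!file.exists(p)) stop(sprintf("'%s' does not exist", p))
  }
  a <- utils::read.csv(csv_a)
  b <- utils::read.csv(csv_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty summary CSV")
  for (nm in list(a, b)) {
    if (!id_col %in% names(nm)) {
      stop(sprintf("identifier column '%s' missing", id_col))
    }
  }
  cmp <- compare_methods(a, b, unit = unit, delta = delta,
                         delta_log = delta_log, alpha = alpha,
                         id_col = id_col, value_col = value_col)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(json = file.path(out_dir, "agreement_report.json"),
                csv = file.path(out_dir, "agreement_report.csv"))
  jsonlite::write_json(comparison_as_list(cmp), paths$json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.csv(comparison_as_table(cmp), paths$csv, row.names = FALSE)
  if (plots) {
    paths$plot_ba <- file.path(out_dir, "bland_altman.png")
    grDevices::png(paths$plot_ba, width = 900, height = 450)
    graphics::par(mfrow = c(1, if (is.null(cmp$bland_altman_log)) 1 else 2))
    plot(cmp$bland_altman_raw)
    if (!is.null(cmp$bland_altman_log)) plot(cmp$bland_altman_log)
    grDevices::dev.off()
  }
  cmp$paths <- paths
  invisible(cmp)
}

ba_as_list <- function(ba) {
  if (is.null(ba)) return(NULL)
  ba$means <- NULL
  ba$diffs <- NULL
  unclass(ba)
}

comparison_as_list <- function(cmp) {
  list(n = cmp$n, unit = cmp$unit, spearman = cmp$spearman,
       bland_altman_raw = ba_as_list(cmp$bland_altman_raw),
       bland_altman_log = ba_as_list(cmp$bland_altman_log),
       shieh_raw = if (!is.null(cmp$shieh_raw)) unclass(cmp$shieh_raw),
       shieh_log = if (!is.null(cmp$shieh_log)) unclass(cmp$shieh_log))
}

comparison_as_table <- function(cmp) {
  row <- function(branch, ba) {
    if (is.null(ba)) return(NULL)
    data.frame(branch = branch, n = ba$n, bias = ba$bias,
               bias_ci_low = ba$bias_ci[1], bias_ci_high = ba$bias_ci[2],
               sd_diff = ba$sd_diff, loa_low = ba$loa[1], loa_high = ba$loa[2],
               loa_width = ba$loa_width, pct_within = ba$pct_within,
               reg_slope = ba$reg_slope, reg_intercept = ba$reg_intercept,
               reg_F = ba$reg_F, reg_p = ba$reg_p)
  }
  out <- rbind(row("raw", cmp$bland_altman_raw),
               row("log", cmp$bland_altman_log))
  out$spearman_rho <- cmp$spearman$rho
  out$spearman_p <- cmp$spearman$p
  out
}

#' Bland-Altman plot
#'
#' Scattergram of differences on averages with horizontal lines for the bias
#' and limits of agreement and the proportional-bias regression line.
#'
#' @param x A `sweclip_bland_altman`.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.sweclip_bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = paste("Mean of methods", x$unit),
                 ylab = paste("Difference (A - B)", x$unit),
                 main = if (x$log_transformed) "Bland-Altman (log)"
                        else "Bland-Altman", ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = x$loa, lty = 2)
  if (is.finite(x$reg_slope)) {
    graphics::abline(x$reg_intercept, x$reg_slope, col = "orange", lwd = 2)
  }
  invisible(x)
}

#' Render a frame with segmentation and ROI overlays
#'
#' Mirrors the GUI's display modes as a file: the frame with the detected (or
#' manual) elastogram box and, optionally, the ROI outline burnt in.
#'
#' @param frame A [frame_image()].
#' @param path Output PNG path.
#' @param geom Optional [elastogram_geometry()] to outline.
#' @param roi Optional `sweclip_roi` (drawn inside the box).
#' @return `path`, invisibly.
#' @export
inspect_frame <- function(frame, path, geom = NULL, roi = NULL) {
  img <- frame$pixels
  draw_box <- function(img, rect, color) {
    ri <- rect_row_idx(rect); ci <- rect_col_idx(rect)
    for (ch in 1:3) {
      img[ri[1], ci, ch] <- color[ch]
      img[ri[length(ri)], ci, ch] <- color[ch]
      img[ri, ci[1], ch] <- color[ch]
      img[ri, ci[length(ci)], ch] <- color[ch]
    }
    img
  }
  if (!is.null(geom)) {
    img <- draw_box(img, geom$box, c(0, 255, 0))
    if (!is.null(roi) && !is.null(roi$cell_id)) {
      for (id in seq_len(max(roi$cell_id))) {
        w <- which(roi$cell_id == id, arr.ind = TRUE)
        cell <- px_rect(geom$box$row0 + min(w[, 1]) - 1L,
                        geom$box$row0 + max(w[, 1]),
                        geom$box$col0 + min(w[, 2]) - 1L,
                        geom$box$col0 + max(w[, 2]))
        img <- draw_box(img, cell, c(255, 255, 0))
      }
    } else if (!is.null(roi)) {
      w <- which(roi$mask, arr.ind = TRUE)
      rect <- px_rect(geom$box$row0 + min(w[, 1]) - 1L,
                      geom$box$row0 + max(w[, 1]),
                      geom$box$col0 + min(w[, 2]) - 1L,
                      geom$box$col0 + max(w[, 2]))
      img <- draw_box(img, rect, c(255, 255, 0))
    }
  }
  png::writePNG(img / 255, path)
  invisible(path)
}
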