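#' Decode one frame's elastogram into an elasticity field
#'
#' Applies [decode_pixel()] to every pixel of the elastogram box: colored
#' pixels get a Young's modulus in kPa, grayscale and out-of-gamut pixels are
#' invalid. Each frame is decoded individually; no temporal averaging.
#'
#' @param frame A [frame_image()].
#' @param geom An [elastogram_geometry()].
#' @param cmap A `sweclip_colormap`.
#' @param scale An [elasticity_scale()] (or bare `e_max` in kPa).
#' @param chroma_tol,gamut_tol,gray_step Decoder tolerances, see
#'   [classify_pixel()].
#' @return Object of class `sweclip_field`: `values` (kPa matrix, `NA` where
#'   invalid), `valid` (logical matrix), `frame_index`, `e_max`.
#' @export
decode_frame <- function(frame, geom, cmap = default_colormap(), scale,
                         chroma_tol = 8, gamut_tol = 12, gray_step = 4) {
  scale <- as_scale(scale)
  px <- crop_pixels(frame, geom$box)
  d <- dim(px)
  dec <- decode_rgb_core(as.numeric(px[, , 1]), as.numeric(px[, , 2]),
                         as.numeric(px[, , 3]), scale, cmap,
                         chroma_tol, gamut_tol, gray_step)
  valid <- matrix(dec$class == "colored", d[1], d[2])
  values <- matrix(dec$value, d[1], d[2])
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, frame_index = frame$index,
                 e_max = scale$e_max),
            class = "sweclip_field")
}

#' @export
print.sweclip_field <- function(x, ...) {
  cat(sprintf("<sweclip_field> frame %d, %d x %d px, %.1f%% valid\n",
              x$frame_index, nrow(x$values), ncol(x$values),
              100 * mean(x$valid)))
  invisible(x)
}

# Statistic vector over a set of kPa values. SD uses the n-1 denominator;
# median/IQR use linear-interpolation quantiles (type 7). n_top counts values
# exceeding the top 2% of the scale maximum, i.e. > top_frac * e_max.
stat_vector <- function(values, n_roi_px, e_max, top_frac = 0.98,
                        top_denominator = c("valid", "roi")) {
  top_denominator <- match.arg(top_denominator)
  n_valid <- length(values)
  fill_pct <- 100 * n_valid / n_roi_px
  if (n_valid == 0L) {
    return(list(n_roi_px = n_roi_px, n_valid = 0L, fill_pct = fill_pct,
                mean = NA_real_, median = NA_real_, sd = NA_real_,
                iqr = NA_real_, max = NA_real_, n_top = NA_integer_,
                pct_top = NA_real_))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  n_top <- sum(values > top_frac * e_max)
  denom <- if (top_denominator == "valid") n_valid else n_roi_px
  list(n_roi_px = n_roi_px, n_valid = n_valid, fill_pct = fill_pct,
       mean = mean(values), median = stats::median(values),
       sd = if (n_valid > 1L) stats::sd(values) else NA_real_,
       iqr = q[2] - q[1], max = max(values),
       n_top = n_top, pct_top = 100 * n_top / denom)
}

#' Per-frame ROI statistics
#'
#' Computes, over the valid (colored) values inside the ROI mask: the fill
#' percentage (share of ROI pixels carrying an elasticity value — the image
#' quality proxy), mean, median, standard deviation (n-1 denominator),
#' interquartile range (linear-interpolation quantiles), maximum, and the
#' number and percentage of values exceeding the top 2% of the scale maximum
#' (`> 0.98 * e_max`). In grid mode the same vector is replicated per cell.
#'
#' @param field A `sweclip_field` from [decode_frame()].
#' @param roi A `sweclip_roi`.
#' @param scale An [elasticity_scale()] (or bare `e_max`).
#' @param top_frac Threshold fraction of `e_max` for the "top" count.
#' @param top_denominator Denominator of `pct_top`: `"valid"` (colored pixels,
#'   default) or `"roi"` (all ROI pixels).
#' @return Object of class `sweclip_frame_stats`; in grid mode the `cells`
#'   element holds a per-cell data frame.
#' @export
frame_stats <- function(field, roi, scale = field$e_max, top_frac = 0.98,
                        top_denominator = c("valid", "roi")) {
  scale <- as_scale(scale)
  top_denominator <- match.arg(top_denominator)
  if (!all(dim(roi$mask) == dim(field$values))) {
    stop("ROI mask does not match the field extent")
  }
  sel <- roi$mask & field$valid
  pooled <- stat_vector(field$values[sel], sum(roi$mask), scale$e_max,
                        top_frac, top_denominator)
  cells <- NULL
  if (!is.null(roi$cell_id)) {
    ids <- seq_len(max(roi$cell_id))
    cells <- do.call(rbind, lapply(ids, function(id) {
      cm <- roi$cell_id == id
      s <- stat_vector(field$values[cm & field$valid], sum(cm), scale$e_max,
                       top_frac, top_denominator)
      data.frame(cell_id = id, as.data.frame(s))
    }))
  }
  structure(c(list(frame_index = field$frame_index), pooled,
              list(cells = cells)),
            class = "sweclip_frame_stats")
}

#' @export
print.sweclip_frame_stats <- function(x, ...) {
  cat(sprintf(
    "<sweclip_frame_stats> frame %d: fill %.1f%%, mean %.2f kPa, median %.2f, sd %.2f\n",
    x$frame_index, x$fill_pct, x$mean, x$median, x$sd))
  invisible(x)
}

#' @export
as.data.frame.sweclip_frame_stats <- function(x, ...) {
  data.frame(frame_index = x$frame_index, n_roi_px = x$n_roi_px,
             n_valid = x$n_valid, fill_pct = x$fill_pct, mean = x$mean,
             median = x$median, sd = x$sd, iqr = x$iqr, max = x$max,
             n_top = x$n_top, pct_top = x$pct_top)
}

#' Clip-level summary of per-frame statistics
#'
#' Arithmetic mean of every per-frame statistic over the frames with at least
#' one valid pixel; frames without an elastogram carry no stiffness
#' information and are excluded rather than imputed.
#'
#' @param stats_list List of `sweclip_frame_stats`.
#' @return Object of class `sweclip_clip_summary`.
#' @export
summarize_clip <- function(stats_list) {
  if (length(stats_list) == 0L) stop("need at least one frame's statistics")
  tab <- do.call(rbind, lapply(stats_list, as.data.frame))
  used <- tab$n_valid > 0L
  fields <- c("fill_pct", "mean", "median", "sd", "iqr", "max", "n_top",
              "pct_top")
  means <- if (any(used)) colMeans(tab[used, fields, drop = FALSE])
           else stats::setNames(rep(NA_real_, length(fields)), fields)
  structure(list(n_frames_total = nrow(tab), n_frames_used = sum(used),
                 means = as.list(means)),
            class = "sweclip_clip_summary")
}

#' @export
print.sweclip_clip_summary <- function(x, ...) {
  cat(sprintf(
    "<sweclip_clip_summary> %d/%d frames used; clip mean %.2f kPa (fill %.1f%%)\n",
    x$n_frames_used, x$n_frames_total,
    if (is.null(x$means$mean)) NA else x$means$mean, x$means$fill_pct))
  invisible(x)
}

#' Analyze a whole clip
#'
#' End-to-end composition: decode every frame with the (fixed) geometry,
#' compute the per-frame statistic vector over the ROI, and summarize across
#' frames. Frame-level failures are collected into the run report without
#' aborting the remaining frames.
#'
#' @param frames List of [frame_image()]s.
#' @param geom An [elastogram_geometry()] (applied to every frame).
#' @param roi A `sweclip_roi`.
#' @param cmap A `sweclip_colormap`.
#' @param scale An [elasticity_scale()] (or bare `e_max` in kPa).
#' @param ... Decoder/statistic options passed to [decode_frame()] and
#'   [frame_stats()].
#' @return Object of class `sweclip_clip_result`: `per_frame` (data frame,
#'   one row per frame in temporal order), `cells` (data frame of per-cell
#'   rows in grid mode, else `NULL`), `summary` (a `sweclip_clip_summary`),
#'   `frame_stats` (the list of `sweclip_frame_stats`), `errors` (named list
#'   of frame-level failures).
#' @export
analyze_clip <- function(frames, geom, roi, cmap = default_colormap(), scale,
                         ...) {
  if (length(frames) == 0L) stop("clip has no frames")
  scale <- as_scale(scale)
  dots <- list(...)
  dec_args <- dots[names(dots) %in% c("chroma_tol", "gamut_tol", "gray_step")]
  st_args <- dots[names(dots) %in% c("top_frac", "top_denominator")]
  stats_list <- list()
  errors <- list()
  for (i in seq_along(frames)) {
    res <- tryCatch({
      field <- do.call(decode_frame,
                       c(list(frames[[i]], geom, cmap, scale), dec_args))
      do.call(frame_stats, c(list(field, roi, scale), st_args))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(frames[[i]]$index)]] <- conditionMessage(res)
    } else {
      stats_list[[length(stats_list) + 1L]] <- res
    }
  }
  if (length(stats_list) == 0L) stop("no frame could be analyzed")
  per_frame <- do.call(rbind, lapply(stats_list, as.data.frame))
  cells <- NULL
  if (!is.null(roi$cell_id)) {
    cells <- do.call(rbind, lapply(stats_list, function(s) {
      if (is.null(s$cells)) return(NULL)
      data.frame(frame_index = s$frame_index, s$cells)
    }))
  }
  structure(list(per_frame = per_frame, cells = cells,
                 summary = summarize_clip(stats_list),
                 frame_stats = stats_list, errors = errors),
            class = "sweclip_clip_result")
}

#' @export
print.sweclip_clip_result <- function(x, ...) {
  print(x$summary)
  if (length(x$errors)) {
    cat(sprintf("  %d frame(s) failed: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
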