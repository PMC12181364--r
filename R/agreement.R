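#' Paired method-comparison series
#'
#' Per-clip values from two analysis methods, matched elementwise. The
#' difference convention throughout is `d = a - b` (method A minus method B,
#' e.g. algorithm minus reference).
#'
#' @param a,b Numeric vectors of equal length `n >= 3`.
#' @param unit Unit label (e.g. `"kPa"`, `"m/s"`).
#' @return Object of class `sweclip_paired`.
#' @export
paired_series <- function(a, b, unit = "") {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop("a and b must be numeric vectors of equal length")
  }
  if (anyNA(a) || anyNA(b)) stop("paired series must not contain NA")
  if (length(a) < 3L) stop("need at least 3 pairs")
  structure(list(a = as.numeric(a), b = as.numeric(b), n = length(a),
                 unit = unit),
            class = "sweclip_paired")
}

as_paired <- function(s, b = NULL, unit = "") {
  if (inherits(s, "sweclip_paired")) s else paired_series(s, b, unit)
}

# all permutations of 1:n (n! x n matrix); used for the exact Spearman p
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged). The two-sided
#' p-value is computed by exact enumeration of all rank permutations for
#' `n <= 8` and by the t approximation with `n - 2` degrees of freedom
#' otherwise.
#'
#' @param s A [paired_series()], or the first numeric vector.
#' @param b Second numeric vector when `s` is a vector.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_correlation <- function(s, b = NULL) {
  s <- as_paired(s, b)
  ra <- rank(s$a); rb <- rank(s$b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("zero rank variance: a series is constant")
  }
  rho <- stats::cor(ra, rb)
  n <- s$n
  if (n <= 8L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(ra, rb[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Proportional-bias regression
#'
#' Ordinary least squares of the between-method differences on the pairwise
#' means (the Bland-Altman trend check). A slope differing from zero
#' indicates proportional bias — the difference changes with the magnitude
#' of the measurement — or non-normally distributed differences.
#'
#' @param means Pairwise means `(a + b) / 2`.
#' @param diffs Differences `a - b`.
#' @return List with `slope`, `intercept`, `F`, `p`, `df` (c(1, n-2)),
#'   `exact_fit` flag.
#' @export
proportional_bias_regression <- function(means, diffs) {
  n <- length(means)
  if (n < 3L || length(diffs) != n) stop("need >= 3 pairs of equal length")
  if (stats::var(means) == 0) stop("means are constant: regression undefined")
  if (stats::var(diffs) == 0) {
    return(list(slope = 0, intercept = mean(diffs), F = 0, p = 1,
                df = c(1L, n - 2L), exact_fit = FALSE))
  }
  fit <- stats::lm(diffs ~ means)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_reg <- sum((stats::fitted(fit) - mean(diffs))^2)
  tol <- .Machine$double.eps^0.5 * sum(diffs^2)
  if (ss_res <= tol) {  # perfect linear relation
    return(list(slope = slope, intercept = intercept, F = Inf, p = 0,
                df = c(1L, n - 2L), exact_fit = TRUE))
  }
  Fstat <- ss_reg / (ss_res / (n - 2))
  list(slope = slope, intercept = intercept, F = Fstat,
       p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
       df = c(1L, n - 2L), exact_fit = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Computes, on the raw or natural-log-transformed series, the mean
#' difference (bias), its 95% confidence interval (t distribution, `n - 1`
#' df), the limits of agreement `bias +/- 1.96 * SD` of the differences (the
#' 1.96 multiplier is fixed, not t-based), the percentage of differences
#' falling inside the limits, and the proportional-bias regression of
#' differences on means. If zero lies inside the bias CI the bias is
#' considered non-significant.
#'
#' @param s A [paired_series()], or the first numeric vector.
#' @param b Second numeric vector when `s` is a vector.
#' @param log_transform Analyze `log(a)` vs `log(b)` (requires positive
#'   values).
#' @param conf Confidence level of the bias CI.
#' @param loa_z Limits-of-agreement multiplier (1.96 for central 95%
#'   coverage).
#' @return Object of class `sweclip_bland_altman`.
#' @export
bland_altman <- function(s, b = NULL, log_transform = FALSE, conf = 0.95,
                         loa_z = 1.96) {
  s <- as_paired(s, b)
  a <- s$a; bb <- s$b
  if (log_transform) {
    if (any(a <= 0) || any(bb <= 0)) {
      stop("log transform requires strictly positive values")
    }
    a <- log(a); bb <- log(bb)
  }
  d <- a - bb
  m <- (a + bb) / 2
  n <- s$n
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- bias + c(-1, 1) * loa_z * sd_diff
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  bias_ci <- bias + c(-1, 1) * tq * sd_diff / sqrt(n)
  eps <- 1e-12 * max(1, abs(loa))
  pct_within <- 100 * mean(d >= loa[1] - eps & d <= loa[2] + eps)
  reg <- if (sd_diff == 0 || stats::var(m) == 0) {
    list(slope = NA_real_, intercept = NA_real_, F = NA_real_, p = NA_real_,
         df = c(1L, n - 2L), exact_fit = FALSE)
  } else {
    proportional_bias_regression(m, d)
  }
  structure(list(n = n, bias = bias, bias_ci = bias_ci, sd_diff = sd_diff,
                 loa = loa, loa_width = loa[2] - loa[1],
                 pct_within = pct_within,
                 bias_significant = !(bias_ci[1] <= 0 && 0 <= bias_ci[2]),
                 reg_slope = reg$slope, reg_intercept = reg$intercept,
                 reg_F = reg$F, reg_p = reg$p, reg_df = reg$df,
                 reg_exact_fit = reg$exact_fit,
                 log_transformed = log_transform, unit = s$unit,
                 conf = conf, loa_z = loa_z,
                 means = m, diffs = d),
            class = "sweclip_bland_altman")
}

#' @export
print.sweclip_bland_altman <- function(x, ...) {
  u <- if (nzchar(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("Bland-Altman%s (n = %d%s)\n",
              if (x$log_transformed) " [log]" else "", x$n, u))
  cat(sprintf("  bias %+.4f  %d%% CI [%.4f, %.4f]  (%ssignificant)\n",
              x$bias, round(100 * x$conf), x$bias_ci[1], x$bias_ci[2],
              if (x$bias_significant) "" else "non-"))
  cat(sprintf("  LoA [%.4f, %.4f]  width %.4f  %.1f%% within\n",
              x$loa[1], x$loa[2], x$loa_width, x$pct_within))
  cat(sprintf("  trend: slope %.4f, intercept %.4f, F(%d,%d) = %.2f, p = %.3g\n",
              x$reg_slope, x$reg_intercept, x$reg_df[1], x$reg_df[2],
              x$reg_F, x$reg_p))
  invisible(x)
}

#' Shieh's exact agreement hypothesis test
#'
#' Tests whether the population central `coverage_p` range of the
#' between-method differences, `mu +/- gamma * sigma` with
#' `gamma = qnorm((1 + coverage_p) / 2)`, lies inside pre-specified agreement
#' margins `delta = (low, high)`. Exact one-sided `1 - alpha` confidence
#' bounds for `mu - gamma * sigma` and `mu + gamma * sigma` are obtained from
#' the noncentral t distribution with `n - 1` degrees of freedom and
#' noncentrality `sqrt(n) * gamma`:
#' `bound = mean -/+ q * sd / sqrt(n)` with `q = qt(1 - alpha, n - 1,
#' ncp = sqrt(n) * gamma)`. Together the bounds form the `1 - 2 * alpha`
#' (default 90%) confidence interval; the null of non-agreement is rejected —
#' the methods are declared interchangeable — exactly when both bounds lie
#' strictly inside the margins.
#'
#' @param diffs Numeric vector of differences, `n >= 3`.
#' @param delta Agreement margins `c(low, high)`. Deliberately has no
#'   default: the margins are a clinical judgement (e.g. a minimal
#'   detectable change) and must be stated by the user.
#' @param alpha One-sided level of each exact bound (default 0.05, i.e. a 90%
#'   two-sided interval).
#' @param coverage_p Central coverage of the population range under test
#'   (default 0.95, `gamma = 1.959964`).
#' @return Object of class `sweclip_shieh`.
#' @export
shieh_agreement_test <- function(diffs, delta, alpha = 0.05,
                                 coverage_p = 0.95) {
  if (!is.numeric(diffs) || anyNA(diffs) || length(diffs) < 3L) {
    stop("diffs must be numeric with n >= 3 and no NA")
  }
  if (length(delta) != 2L || anyNA(delta) || delta[1] >= delta[2]) {
    stop("delta must be c(low, high) with low < high")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must lie in (0, 0.5)")
  }
  if (coverage_p <= 0 || coverage_p >= 1) stop("coverage_p must lie in (0, 1)")
  n <- length(diffs)
  gamma <- stats::qnorm((1 + coverage_p) / 2)
  xbar <- mean(diffs)
  s <- stats::sd(diffs)
  # pnt emits a blanket precision warning for large noncentrality; the
  # attained accuracy is orders of magnitude inside the tolerances that
  # matter here (checked against a parametric bootstrap in the test suite)
  q <- withCallingHandlers(
    stats::qt(1 - alpha, df = n - 1, ncp = sqrt(n) * gamma),
    warning = function(w) {
      if (grepl("full precision", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  bound_low <- xbar - q * s / sqrt(n)
  bound_high <- xbar + q * s / sqrt(n)
  reject <- delta[1] < bound_low && bound_high < delta[2]
  structure(list(n = n, mean = xbar, sd = s, gamma = gamma, alpha = alpha,
                 conf = 1 - 2 * alpha, coverage_p = coverage_p,
                 bound_low = bound_low, bound_high = bound_high,
                 delta = as.numeric(delta), reject_h0 = reject),
            class = "sweclip_shieh")
}

#' @export
print.sweclip_shieh <- function(x, ...) {
  cat(sprintf("Shieh exact agreement test (n = %d)\n", x$n))
  cat(sprintf("  %d%% CI for mu -/+ %.3f sigma: [%.4f, %.4f]\n",
              round(100 * x$conf), x$gamma, x$bound_low, x$bound_high))
  cat(sprintf("  margins [%.4f, %.4f]: %s\n", x$delta[1], x$delta[2],
              if (x$reject_h0) {
                "H0 rejected - methods interchangeable within the margins"
              } else {
                "H0 not rejected - interchangeability not demonstrated"
              }))
  invisible(x)
}

#' Full method-comparison report
#'
#' Runs the complete validation workflow on matched per-clip summaries:
#' Spearman correlation, Bland-Altman on the raw and (for positive data)
#' log-transformed series, and — when agreement margins are supplied —
#' Shieh's exact test on both branches.
#'
#' @param a,b Numeric per-clip values of methods A and B, or data frames with
#'   an identifier column `id_col` and a value column `value_col`.
#' @param unit Unit label.
#' @param delta Agreement margins for the raw-scale Shieh test, or `NULL`.
#' @param delta_log Margins for the log-scale Shieh test, or `NULL`.
#' @param alpha One-sided level for the Shieh bounds.
#' @param id_col,value_col Column names used when `a` and `b` are data
#'   frames; rows are matched by identifier and unmatched identifiers are
#'   dropped with a warning.
#' @return Object of class `sweclip_comparison`.
#' @export
compare_methods <- function(a, b, unit = "", delta = NULL, delta_log = NULL,
                            alpha = 0.05, id_col = "clip",
                            value_col = "mean") {
  if (is.data.frame(a) || is.data.frame(b)) {
    if (!is.data.frame(a) || !is.data.frame(b)) {
      stop("either both or neither input may be a data frame")
    }
    for (df in list(a, b)) {
      if (!all(c(id_col, value_col) %in% names(df))) {
        stop(sprintf("data frames need columns '%s' and '%s'",
                     id_col, value_col))
      }
    }
    common <- intersect(a[[id_col]], b[[id_col]])
    dropped <- setdiff(union(a[[id_col]], b[[id_col]]), common)
    if (length(dropped)) {
      warning(sprintf("%d unmatched clip id(s) excluded: %s", length(dropped),
                      paste(utils::head(dropped, 10), collapse = ", ")))
    }
    a <- a[[value_col]][match(common, a[[id_col]])]
    b <- b[[value_col]][match(common, b[[id_col]])]
  }
  s <- paired_series(a, b, unit = unit)
  pos <- all(s$a > 0) && all(s$b > 0)
  res <- list(
    n = s$n, unit = unit,
    spearman = spearman_correlation(s),
    bland_altman_raw = bland_altman(s),
    bland_altman_log = if (pos) bland_altman(s, log_transform = TRUE) else NULL,
    shieh_raw = if (!is.null(delta)) {
      shieh_agreement_test(s$a - s$b, delta, alpha = alpha)
    },
    shieh_log = if (!is.null(delta_log) && pos) {
      shieh_agreement_test(log(s$a) - log(s$b), delta_log, alpha = alpha)
    })
  structure(res, class = "sweclip_comparison")
}

#' @export
print.sweclip_comparison <- function(x, ...) {
  cat(sprintf("Method comparison, n = %d%s\n", x$n,
              if (nzchar(x$unit)) paste0(" (", x$unit, ")") else ""))
  cat(sprintf("  Spearman rho = %.4f, p = %.3g (%s)\n",
              x$spearman$rho, x$spearman$p, x$spearman$method))
  print(x$bland_altman_raw)
  if (!is.null(x$bland_altman_log)) print(x$bland_altman_log)
  if (!is.null(x$shieh_raw)) print(x$shieh_raw)
  if (!is.null(x$shieh_log)) print(x$shieh_log)
  invisible(x)
}
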