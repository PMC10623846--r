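## Two-segment linear-regression changepoint detection on cumulative curves:
## every candidate split VAF is evaluated by fitting separate OLS lines to
## the low-VAF (vaf <= split) and high-VAF (vaf >= split) portions — the two
## regression lines share the split point, where they meet — and the winning
## split maximizes the signed slope difference (low minus high).

#' Enumerate all candidate splits of a cumulative curve
#'
#' For each distinct VAF value that leaves at least `min_seg` points in both
#' the low segment (VAF at or below the split) and the high segment (VAF at
#' or above it; the split point belongs to both segments), fits OLS lines to
#' both segments and records the signed slope difference (low slope minus
#' high slope).
#'
#' @param curve A `cumulative_curve` (or any data frame with `vaf` and
#'   `value` columns, `vaf` nondecreasing).
#' @param min_seg Minimum points per segment (default 3, so that segment
#'   slopes, R\eqn{^2} and slope p-values are all defined). The default
#'   suits smooth cumulative curves, whose running statistics vary slowly;
#'   for curves with independent per-point noise the slope of a short
#'   segment is noise-dominated (a k-point slope has standard deviation
#'   about sigma * sqrt(12 / k^3) / step) and `min_seg` should grow with the
#'   curve — about a quarter of the points is a robust guard.
#' @return A tibble with one row per candidate: `split_vaf`, `n_low`,
#'   `n_high`, `slope_low`, `slope_high`, `slope_difference`.
#' @export
enumerate_splits <- function(curve, min_seg = 3) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  if (n < 2 * min_seg) {
    stop_mgmtvaf(sprintf("curve needs >= %d points for min_seg = %d",
                         2 * min_seg, min_seg), "mgmtvaf_argument_error")
  }
  splits <- unique(pts$vaf)
  rows <- lapply(splits, function(s) {
    low <- pts$vaf <= s
    high <- pts$vaf >= s
    n_low <- sum(low); n_high <- sum(high)
    if (n_low < min_seg || n_high < min_seg) return(NULL)
    # segments can sit on a VAF tie block; a constant-x segment cannot be fit
    if (length(unique(pts$vaf[low])) < 2 || length(unique(pts$vaf[high])) < 2) {
      return(NULL)
    }
    f_low <- fit_line(pts$vaf[low], pts$value[low])
    f_high <- fit_line(pts$vaf[high], pts$value[high])
    tibble::tibble(split_vaf = s, n_low = n_low, n_high = n_high,
                   slope_low = f_low$slope, slope_high = f_high$slope,
                   slope_difference = f_low$slope - f_high$slope)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop_mgmtvaf("no admissible split leaves min_seg fittable points per segment",
                 "mgmtvaf_argument_error")
  }
  do.call(rbind, rows)
}

#' Two-segment regression changepoint fit of a cumulative curve
#'
#' Exhaustively evaluates every candidate split (see [enumerate_splits()])
#' and returns the one maximizing the signed slope difference, low-segment
#' slope minus high-segment slope; ties are broken toward the smallest
#' split VAF. The split point belongs to both segments, so the two fitted
#' lines describe the curve on either side of a shared knee. On cumulative
#' positivity curves this locates the VAF below which the positivity rate
#' drops steeply.
#'
#' @inheritParams enumerate_splits
#' @return A `changepoint_fit` list: `split_vaf`, `low_fit` and `high_fit`
#'   (`regression_result`s for the two segments), `slope_difference`,
#'   `candidates_evaluated`, and the per-candidate `table`.
#' @export
#' @examples
#' curve <- make_hinge_curve(knee = 0.2, low_slope = 1, plateau = 0.2,
#'                           grid_step = 0.02)
#' two_part_fit(curve)$split_vaf  # 0.2
two_part_fit <- function(curve, min_seg = 3) {
  pts <- curve_points(curve)
  tab <- enumerate_splits(curve, min_seg = min_seg)
  best <- which(tab$slope_difference == max(tab$slope_difference))[1]
  split <- tab$split_vaf[best]
  low <- pts$vaf <= split
  high <- pts$vaf >= split
  structure(
    list(split_vaf = split,
         low_fit = fit_line(pts$vaf[low], pts$value[low]),
         high_fit = fit_line(pts$vaf[high], pts$value[high]),
         slope_difference = tab$slope_difference[best],
         candidates_evaluated = nrow(tab),
         table = tab),
    class = "changepoint_fit"
  )
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf(
    "Two-segment changepoint at VAF = %.4g (%d candidates evaluated)\n",
    x$split_vaf, x$candidates_evaluated))
  cat(sprintf("  low  segment: slope %.4g (R^2 %.3f, n %d)\n",
              x$low_fit$slope, x$low_fit$r_squared, x$low_fit$n))
  cat(sprintf("  high segment: slope %.4g (R^2 %.3f, n %d)\n",
              x$high_fit$slope, x$high_fit$r_squared, x$high_fit$n))
  cat(sprintf("  slope difference (low - high): %.4g\n", x$slope_difference))
  invisible(x)
}

curve_points <- function(curve) {
  if (!is.data.frame(curve) || !all(c("vaf", "value") %in% names(curve))) {
    stop_mgmtvaf("curve must have vaf and value columns", "mgmtvaf_argument_error")
  }
  if (is.unsorted(curve$vaf)) {
    stop_mgmtvaf("curve vaf values must be nondecreasing", "mgmtvaf_argument_error")
  }
  tibble::tibble(vaf = curve$vaf, value = curve$value)
}
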