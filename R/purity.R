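## Tumor purity from driver VAF, simple OLS, and the microscopy-vs-VAF
## cellularity discrepancy analysis.

#' Estimate tumor cellularity from driver-mutation VAF
#'
#' Clonal heterozygous drivers put one mutant allele in every tumor cell, so
#' the tumor-cell fraction is approximately twice the VAF. The estimate is
#' expressed in percent and capped at 100% for the rare samples with
#' VAF > 0.5.
#'
#' @param vaf Driver-mutation variant allelic frequency/-ies in \[0, 1\].
#' @return Estimated cellularity in percent: `min(2 * vaf * 100, 100)`.
#' @export
#' @examples
#' cellularity_from_vaf(0.18)  # 36
#' cellularity_from_vaf(0.6)   # 100 (capped)
cellularity_from_vaf <- function(vaf) {
  if (any(!is.finite(vaf)) || any(vaf < 0 | vaf > 1)) {
    stop_mgmtvaf("vaf must lie in [0, 1]", "mgmtvaf_domain_error")
  }
  pmin(2 * vaf * 100, 100)
}

#' Ordinary least-squares line fit
#'
#' Closed-form simple linear regression reporting slope, intercept, R\eqn{^2}
#' and the two-sided p-value for slope deviation from zero (t distribution,
#' n - 2 degrees of freedom). For a constant response (zero total sum of
#' squares) the slope and R\eqn{^2} are 0 and the p-value 1.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`, `x` not constant.
#' @return A `regression_result` list: `slope`, `intercept`, `r_squared`,
#'   `p_slope`, `n`.
#' @export
fit_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2 || length(y) != n) {
    stop_mgmtvaf("fit_line requires at least 2 complete (x, y) pairs",
                 "mgmtvaf_argument_error")
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    stop_mgmtvaf("fit_line: all x values identical (degenerate design)",
                 "mgmtvaf_argument_error")
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  rss <- max(rss, 0)  # guard tiny negative from cancellation
  r_squared <- if (syy > 0) 1 - rss / syy else 0
  p_slope <- if (n > 2) {
    se <- sqrt(rss / (n - 2) / sxx)
    if (se == 0) {
      if (slope == 0) 1 else 0
    } else {
      2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
    }
  } else {
    NA_real_  # exact fit through two points carries no slope test
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, p_slope = p_slope, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_slope))
  invisible(x)
}

#' Microscopy-based versus VAF-based cellularity discrepancy
#'
#' For every sample with a microscopic cellularity estimate, computes the
#' difference (microscopic minus VAF-based, in percentage points) and
#' regresses it on driver VAF. A negative slope indicates that microscopy
#' overestimates cellularity in low-purity samples relative to the VAF-based
#' estimate.
#'
#' @param cohort A `glioma_cohort` with `micro_cellularity` present on at
#'   least two samples (QNS samples are excluded).
#' @return A list with `per_sample` (tibble: sample_id, driver_vaf,
#'   micro_cellularity, vaf_cellularity, difference) and `fit`
#'   (a `regression_result` of difference on VAF).
#' @export
cellularity_discrepancy <- function(cohort) {
  cohort <- ensure_cohort(cohort)
  usable <- usable_samples(cohort)
  usable <- usable[!is.na(usable$micro_cellularity), , drop = FALSE]
  if (nrow(usable) < 2) {
    stop_mgmtvaf("cellularity_discrepancy requires >= 2 samples with micro_cellularity",
                 "mgmtvaf_argument_error")
  }
  vaf_cell <- cellularity_from_vaf(usable$driver_vaf)
  diff <- usable$micro_cellularity - vaf_cell
  per_sample <- tibble::tibble(
    sample_id = usable$sample_id,
    driver_vaf = usable$driver_vaf,
    micro_cellularity = usable$micro_cellularity,
    vaf_cellularity = vaf_cell,
    difference = diff
  )
  list(per_sample = per_sample, fit = fit_line(usable$driver_vaf, diff))
}
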