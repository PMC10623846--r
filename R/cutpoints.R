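## Fisher-exact 2x2 machinery and exhaustive VAF cutpoint scanning, following
## the Cutoff Finder approach of dichotomizing the cohort at every candidate
## cutpoint and minimizing the Fisher two-sided p-value.

#' Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by conditioning on the table margins and
#' summing the hypergeometric probabilities of all tables whose probability
#' does not exceed that of the observed table (the probability-mass-summation
#' convention, with a relative tolerance of 1e-7 on the comparison). The
#' odds ratio reported is the unconditional sample estimate `a*d / (b*c)`,
#' infinite when `b*c = 0`.
#'
#' Rows are the dichotomized grouping (e.g., VAF at/above vs below a cutoff,
#' or assay A vs assay B); columns are POSITIVE vs NEGATIVE calls.
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise: `a` row-1
#'   positive, `b` row-1 negative, `c` row-2 positive, `d` row-2 negative.
#'   Alternatively `a` may be a length-4 vector or a 2x2 matrix.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact(79, 88, 101, 200)  # p ~= 0.004
#' fisher_exact(1, 1, 1, 1)        # p = 1
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) a <- as.vector(t(a))
  if (length(a) == 4 && is.null(b)) {
    d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1]
  }
  cells <- base::c(a, b, c, d)  # base:: because `c` is an argument here
  if (length(cells) != 4 || any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop_mgmtvaf("fisher_exact requires four nonnegative integer counts",
                 "mgmtvaf_argument_error")
  }
  if (sum(cells) == 0) {
    stop_mgmtvaf("fisher_exact: all-zero table", "mgmtvaf_argument_error")
  }
  ## condition on margins: x = row-1 positives follows a hypergeometric
  ## distribution over its admissible support
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  support <- max(0, col1 - row2):min(col1, row1)
  dens <- stats::dhyper(support, row1, row2, col1)
  d_obs <- stats::dhyper(a, row1, row2, col1)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  p <- min(p, 1)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf   # 0/0 is undefined; x/0 with x > 0 is Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p)
}

#' Scan all candidate VAF cutpoints with Fisher's exact test
#'
#' Reimplements the Fisher-exact mode of cutpoint scanning: candidate
#' cutpoints are the midpoints between consecutive distinct observed VAFs;
#' at each candidate the cohort is split into samples with VAF at/above
#' versus below the cutpoint, a 2x2 table against POSITIVE/NEGATIVE calls is
#' formed, and the two-sided Fisher p-value and sample odds ratio are
#' recorded. The optimal cutpoint minimizes the p-value, ties broken toward
#' the smallest cutpoint. No multiple-testing correction is applied across
#' candidates: the minimal p-value is an optimistically selected raw value
#' and must not be read as a hypothesis test.
#'
#' @param cohort A `glioma_cohort` (or coercible data frame) with binary
#'   calls; EQUIVOCAL/QNS samples are excluded with a warning.
#' @param min_per_side Minimum number of samples required on each side of a
#'   candidate cutpoint (default 5).
#' @return A `cutoff_scan` list: `candidates` (tibble with `cutoff`,
#'   `n_above`, `n_below`, `pos_above`, `pos_below`, `odds_ratio`,
#'   `p_value`), `optimal_cutoff`, `optimal_p`, `degenerate` (TRUE when all
#'   usable calls are identical), `n_used`.
#' @export
scan_vaf_cutoffs <- function(cohort, min_per_side = 5) {
  cohort <- ensure_cohort(cohort)
  cohort <- binary_call_samples(cohort)
  n <- nrow(cohort)
  if (n < 2 * min_per_side) {
    stop_mgmtvaf(sprintf(
      "cutpoint scan requires >= %d samples with binary calls (have %d)",
      2 * min_per_side, n), "mgmtvaf_argument_error")
  }
  ord <- order(cohort$driver_vaf, method = "radix")
  vaf <- cohort$driver_vaf[ord]
  pos <- as.integer(cohort$mgmt_call[ord] == "POSITIVE")
  degenerate <- length(unique(pos)) == 1L

  distinct <- unique(vaf)
  mids <- (distinct[-length(distinct)] + distinct[-1]) / 2
  rows <- lapply(mids, function(cut) {
    above <- vaf >= cut
    n_above <- sum(above); n_below <- sum(!above)
    if (n_above < min_per_side || n_below < min_per_side) return(NULL)
    a <- sum(pos[above]); b <- n_above - a
    cc <- sum(pos[!above]); dd <- n_below - cc
    ft <- fisher_exact(a, b, cc, dd)
    tibble::tibble(cutoff = cut, n_above = n_above, n_below = n_below,
                   pos_above = a, pos_below = cc,
                   odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop_mgmtvaf("no candidate cutpoint leaves min_per_side samples on both sides",
                 "mgmtvaf_argument_error")
  }
  candidates <- do.call(rbind, rows)
  best <- which(candidates$p_value == min(candidates$p_value))[1]
  structure(
    list(candidates = candidates,
         optimal_cutoff = candidates$cutoff[best],
         optimal_p = candidates$p_value[best],
         degenerate = degenerate,
         n_used = n,
         min_per_side = min_per_side),
    class = "cutoff_scan"
  )
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "VAF cutpoint scan over %d candidates (n = %d, min %d per side)\n",
    nrow(x$candidates), x$n_used, x$min_per_side))
  cat(sprintf("  optimal cutoff %.4g with raw Fisher p = %.4g%s\n",
              x$optimal_cutoff, x$optimal_p,
              if (x$degenerate) " [degenerate: all calls identical]" else ""))
  cat("  note: minimal p over an exhaustive scan; no multiplicity correction\n")
  invisible(x)
}

#' Compare a continuous measure between two groups
#'
#' Two-sided Student's t-test (equal variances, unpaired) or Mann-Whitney U
#' (Wilcoxon rank-sum) test, as used for above- versus below-cutoff score
#' comparisons. Constant identical groups return p = 1 rather than an error.
#'
#' @param x_above,x_below Numeric vectors, each with at least 2 values.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(x_above, x_below, method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  x_above <- x_above[is.finite(x_above)]
  x_below <- x_below[is.finite(x_below)]
  if (length(x_above) < 2 || length(x_below) < 2) {
    stop_mgmtvaf("both groups need >= 2 finite values", "mgmtvaf_argument_error")
  }
  if (method == "t_test") {
    if (stats::sd(x_above) == 0 && stats::sd(x_below) == 0) {
      return(if (mean(x_above) == mean(x_below)) 1 else 0)
    }
    stats::t.test(x_above, x_below, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x_above, x_below, exact = NULL)$p.value)
  }
}
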