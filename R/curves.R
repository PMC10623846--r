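## VAF-ranked cumulative curves: samples are sorted by increasing VAF and a
## running statistic (mean positivity, mean score, median score) is computed
## over each prefix. The final point always equals the whole-cohort value.

new_cumulative_curve <- function(vaf, value, n_at_point, statistic) {
  structure(
    tibble::tibble(vaf = vaf, value = value, n = n_at_point),
    statistic = statistic,
    class = c("cumulative_curve", class(tibble::tibble()))
  )
}

## Stable (VAF, sample_id) ordering shared by both curve builders. Within a
## tie block only the block-final cumulative value is order-invariant; callers
## are documented accordingly.
rank_by_vaf <- function(cohort) {
  cohort[order(cohort$driver_vaf, cohort$sample_id, method = "radix"), ,
         drop = FALSE]
}

#' Cumulative mean positivity curve ranked by VAF
#'
#' Samples are ranked by increasing driver VAF (ties broken by sample_id) and
#' point k of the curve is the fraction of POSITIVE calls among the k
#' lowest-VAF samples. EQUIVOCAL and QNS samples are excluded with a warning.
#'
#' @param cohort A `glioma_cohort` (or coercible data frame) whose retained
#'   samples carry binary POSITIVE/NEGATIVE calls.
#' @return A `cumulative_curve` tibble with columns `vaf`, `value` (running
#'   positivity in \[0, 1\]) and `n` (prefix size), and a `statistic`
#'   attribute of `"MEAN_POSITIVITY"`.
#' @export
cumulative_positivity <- function(cohort) {
  cohort <- ensure_cohort(cohort)
  cohort <- binary_call_samples(cohort)
  if (nrow(cohort) == 0) {
    stop_mgmtvaf("no samples with binary POSITIVE/NEGATIVE calls",
                 "mgmtvaf_argument_error")
  }
  ranked <- rank_by_vaf(cohort)
  pos <- as.numeric(ranked$mgmt_call == "POSITIVE")
  k <- seq_along(pos)
  new_cumulative_curve(ranked$driver_vaf, cumsum(pos) / k, k, "MEAN_POSITIVITY")
}

#' Cumulative mean or median MGMT score curve ranked by VAF
#'
#' As [cumulative_positivity()], but the running statistic is the mean or
#' median of `mgmt_score` over each VAF-ranked prefix. Samples without a
#' score, and EQUIVOCAL/QNS samples, are excluded with a warning. Running
#' medians over even-sized prefixes use the midpoint of the two middle
#' values.
#'
#' @param cohort A `glioma_cohort` (or coercible data frame).
#' @param stat `"mean"` or `"median"`.
#' @return A `cumulative_curve` with statistic `"MEAN_SCORE"` or
#'   `"MEDIAN_SCORE"`.
#' @export
cumulative_score <- function(cohort, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  cohort <- ensure_cohort(cohort)
  cohort <- binary_call_samples(cohort)
  has_score <- !is.na(cohort$mgmt_score)
  if (any(!has_score)) {
    warning(sprintf("excluded %d sample(s) without mgmt_score", sum(!has_score)),
            call. = FALSE)
    cohort <- cohort[has_score, , drop = FALSE]
  }
  if (nrow(cohort) == 0) {
    stop_mgmtvaf("no usable samples with mgmt_score", "mgmtvaf_argument_error")
  }
  ranked <- rank_by_vaf(cohort)
  s <- ranked$mgmt_score
  k <- seq_along(s)
  value <- if (stat == "mean") {
    cumsum(s) / k
  } else {
    vapply(k, function(i) stats::median(s[seq_len(i)]), numeric(1))
  }
  new_cumulative_curve(ranked$driver_vaf, value, k,
                       if (stat == "mean") "MEAN_SCORE" else "MEDIAN_SCORE")
}

#' Build a cumulative curve object from raw point vectors
#'
#' Lower-level constructor used by the simulation helpers and anywhere a
#' curve is assembled outside the two cohort-facing builders.
#'
#' @param vaf Nondecreasing numeric vector of VAFs.
#' @param value Numeric vector, same length as `vaf`.
#' @param statistic Statistic label; one of `"MEAN_POSITIVITY"`,
#'   `"MEAN_SCORE"`, `"MEDIAN_SCORE"`.
#' @param n_at_point Optional prefix sizes (defaults to 1..length).
#' @return A `cumulative_curve`.
#' @export
cumulative_curve <- function(vaf, value,
                             statistic = c("MEAN_POSITIVITY", "MEAN_SCORE",
                                           "MEDIAN_SCORE"),
                             n_at_point = seq_along(vaf)) {
  statistic <- match.arg(statistic)
  if (length(vaf) != length(value)) {
    stop_mgmtvaf("vaf and value must have equal length", "mgmtvaf_argument_error")
  }
  if (is.unsorted(vaf)) {
    stop_mgmtvaf("vaf must be nondecreasing", "mgmtvaf_argument_error")
  }
  if (statistic == "MEAN_POSITIVITY" && any(value < 0 | value > 1)) {
    stop_mgmtvaf("positivity values must lie in [0, 1]", "mgmtvaf_argument_error")
  }
  new_cumulative_curve(vaf, value, n_at_point, statistic)
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat("<cumulative_curve> ", attr(x, "statistic"), ", ", nrow(x),
      " points, final value ", format(x$value[nrow(x)], digits = 4), "\n",
      sep = "")
  NextMethod()
}

#' Write a cumulative curve as two-column TSV
#'
#' @param curve A `cumulative_curve`.
#' @param path Output path; a sidecar `<path>.json` records the statistic
#'   and length.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cumulative_curve"))
  readr::write_tsv(tibble::tibble(vaf = curve$vaf, value = curve$value),
                   path, progress = FALSE)
  meta <- list(statistic = attr(curve, "statistic"), n_points = nrow(curve))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
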