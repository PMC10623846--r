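## False-negative risk flagging, the cohort-level false-negative rate
## estimate, labeled assay comparisons, and the full pipeline report.

#' Flag samples at risk of a false-negative MGMT call
#'
#' A sample is flagged when its MGMT call is NEGATIVE and its driver VAF
#' lies below the reliability cutoff for its subtype: in such paucicellular
#' specimens the methylation signal of a truly methylated tumor may be
#' diluted below the assay cutoff by non-neoplastic DNA. Flagged samples
#' carry a recommendation for orthogonal re-testing with a more sensitive
#' method (DNA methylation array or ddPCR).
#'
#' @param cohort A `glioma_cohort` (or coercible data frame); EQUIVOCAL and
#'   QNS samples are excluded with a warning.
#' @param cutoffs Named subtype-to-VAF cutoff vector covering every subtype
#'   present; defaults to [default_vaf_cutoffs()] (the regression-derived
#'   set).
#' @return A `risk_flag_report`: tibble with `sample_id`, `subtype`,
#'   `mgmt_call`, `driver_vaf`, `subtype_cutoff_used`, `flagged`, `reason`,
#'   `recommendation`; the cutoff set name is kept in the `cutoff_set`
#'   attribute.
#' @export
flag_false_negative_risk <- function(cohort, cutoffs = default_vaf_cutoffs()) {
  cohort <- ensure_cohort(cohort)
  cohort <- binary_call_samples(cohort)
  present <- unique(cohort$subtype)
  missing_cut <- setdiff(present, names(cutoffs))
  if (length(missing_cut) > 0) {
    stop_mgmtvaf(paste0("no VAF cutoff supplied for subtype(s): ",
                        paste(missing_cut, collapse = ", ")),
                 "mgmtvaf_argument_error")
  }
  cut_used <- unname(cutoffs[cohort$subtype])
  flagged <- cohort$mgmt_call == "NEGATIVE" & cohort$driver_vaf < cut_used
  report <- tibble::tibble(
    sample_id = cohort$sample_id,
    subtype = cohort$subtype,
    mgmt_call = cohort$mgmt_call,
    driver_vaf = cohort$driver_vaf,
    subtype_cutoff_used = cut_used,
    flagged = flagged,
    reason = ifelse(
      flagged,
      sprintf("NEGATIVE call with driver VAF %.3f below the %.3f reliability cutoff",
              cohort$driver_vaf, cut_used),
      ""),
    recommendation = ifelse(
      flagged,
      "at risk of false-negative result; recommend orthogonal re-testing by DNA methylation array or ddPCR",
      "")
  )
  structure(report, cutoff_set = attr(cutoffs, "cutoff_set") %||% "custom",
            class = base::c("risk_flag_report", class(report)))
}

#' @export
print.risk_flag_report <- function(x, ...) {
  if ("flagged" %in% names(x)) {  # column subsets of the report print plainly
    cat(sprintf("False-negative risk report (%s cutoffs): %d of %d samples flagged\n",
                attr(x, "cutoff_set"), sum(x$flagged), nrow(x)))
  }
  NextMethod()
}

#' Estimate the cohort-level false-negative rate
#'
#' Multiplies the fraction of samples falling below the VAF reliability
#' cutoff by the expected prevalence of MGMT promoter methylation in that
#' tumor type: samples below the cutoff are at risk, and among them roughly
#' the prevalence fraction would be truly methylated yet prone to read out
#' negative.
#'
#' @param frac_below_cutoff Fraction of samples below the cutoff, in
#'   \[0, 1\].
#' @param methylation_prevalence Expected methylation prevalence, in
#'   \[0, 1\].
#' @return An `fn_rate_estimate` list: `rate` (the product, a proportion)
#'   and `percent` (the same value formatted in percent to one decimal).
#' @export
#' @examples
#' estimate_fn_rate(0.126, 0.35)  # 4.4% of samples
estimate_fn_rate <- function(frac_below_cutoff, methylation_prevalence) {
  ok <- function(p) is.finite(p) && p >= 0 && p <= 1
  if (!ok(frac_below_cutoff) || !ok(methylation_prevalence)) {
    stop_mgmtvaf("both arguments must lie in [0, 1]", "mgmtvaf_domain_error")
  }
  rate <- frac_below_cutoff * methylation_prevalence
  structure(list(rate = rate, percent = round(100 * rate, 1)),
            class = "fn_rate_estimate")
}

#' @export
print.fn_rate_estimate <- function(x, ...) {
  cat(sprintf("Estimated false-negative rate: %.1f%% of samples\n", x$percent))
  invisible(x)
}

#' Labeled 2x2 assay comparison
#'
#' Wraps [fisher_exact()] with labeled positive proportions for comparing
#' the positivity of two assays (or two sample strata). Percents are
#' rounded to integers in the printed output; the returned record keeps
#' full precision.
#'
#' @param a,b Row 1 (first assay/stratum): positive and negative counts.
#' @param c,d Row 2 (second assay/stratum): positive and negative counts.
#' @param labels Character vector of two row labels.
#' @return An `assay_comparison` list: per-row `n`, `positive`,
#'   `prop_positive`, plus `odds_ratio` and `p_value`.
#' @export
#' @examples
#' assay_comparison(79, 88, 101, 200, labels = c("array", "pyrosequencing"))
assay_comparison <- function(a, b, c, d, labels = base::c("group1", "group2")) {
  pos2 <- c  # `c` masks base::c inside this function
  counts <- base::c(a, b, pos2, d)
  if (length(counts) != 4 || any(!is.finite(counts)) || any(counts < 0)) {
    stop_mgmtvaf("assay_comparison requires four nonnegative counts",
                 "mgmtvaf_argument_error")
  }
  if ((a + b) == 0 || (pos2 + d) == 0) {
    stop_mgmtvaf("assay_comparison: a row has zero total", "mgmtvaf_argument_error")
  }
  if ((a + pos2) == 0 || (b + d) == 0) {
    stop_mgmtvaf("assay_comparison: a column has zero total", "mgmtvaf_argument_error")
  }
  ft <- fisher_exact(a, b, pos2, d)
  structure(
    list(labels = labels,
         n = base::c(a + b, pos2 + d),
         positive = base::c(a, pos2),
         prop_positive = base::c(a / (a + b), pos2 / (pos2 + d)),
         odds_ratio = ft$odds_ratio,
         p_value = ft$p_value),
    class = "assay_comparison"
  )
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat(sprintf("%s: %d/%d positive (%d%%) vs %s: %d/%d positive (%d%%)\n",
              x$labels[1], x$positive[1], x$n[1], round(100 * x$prop_positive[1]),
              x$labels[2], x$positive[2], x$n[2], round(100 * x$prop_positive[2])))
  cat(sprintf("  Fisher exact: OR = %.3g, p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Run the full VAF quality-assurance pipeline on a cohort
#'
#' Chains the analysis stages: cohort summary, cumulative positivity and
#' score curves, Fisher-exact cutpoint scan, two-segment changepoint fit on
#' the positivity curve, and false-negative risk flagging. Writes a
#' machine-readable JSON report plus TSV tables to `out_dir`. All outputs
#' are deterministic functions of the input cohort and options (no
#' timestamps), so a rerun reproduces the bundle byte-for-byte.
#'
#' @param cohort A `glioma_cohort` (or coercible data frame).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param cutoffs Subtype VAF cutoffs for flagging
#'   ([default_vaf_cutoffs()]).
#' @param min_per_side Guard for the cutpoint scan.
#' @param min_seg Minimum points per changepoint segment.
#' @return A `vafqc_report` list with elements `summary`, `positivity_curve`,
#'   `score_curve`, `scan`, `changepoint`, `flags`, `options`.
#' @export
run_report <- function(cohort, out_dir = NULL,
                       cutoffs = default_vaf_cutoffs(),
                       min_per_side = 5, min_seg = 3) {
  cohort <- ensure_cohort(cohort)
  summary <- summarize_cohort(cohort)
  pos_curve <- cumulative_positivity(cohort)
  score_curve <- if (any(!is.na(cohort$mgmt_score))) {
    suppressWarnings(cumulative_score(cohort, "mean"))
  } else NULL
  scan <- scan_vaf_cutoffs(cohort, min_per_side = min_per_side)
  cpt <- two_part_fit(pos_curve, min_seg = min_seg)
  flags <- flag_false_negative_risk(cohort, cutoffs = cutoffs)

  report <- structure(
    list(summary = summary,
         positivity_curve = pos_curve,
         score_curve = score_curve,
         scan = scan,
         changepoint = cpt,
         flags = flags,
         options = list(cutoffs = as.list(cutoffs),
                        cutoff_set = attr(flags, "cutoff_set"),
                        min_per_side = min_per_side, min_seg = min_seg,
                        provenance = attr(cohort, "provenance"))),
    class = "vafqc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.vafqc_report <- function(x, ...) {
  cat("== VAF quality-assurance report ==\n")
  cat("Samples:", x$summary$n, "\n")
  print(x$scan)
  print(x$changepoint)
  cat(sprintf("Flagged at false-negative risk: %d of %d\n",
              sum(x$flags$flagged), nrow(x$flags)))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(as.data.frame(report$flags), p("flags.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(as.data.frame(report$scan$candidates), p("scan.tsv"),
                   progress = FALSE)
  readr::write_tsv(as.data.frame(report$changepoint$table),
                   p("changepoint_candidates.tsv"), progress = FALSE)
  write_curve(report$positivity_curve, p("positivity_curve.tsv"))
  if (!is.null(report$score_curve)) {
    write_curve(report$score_curve, p("score_curve.tsv"))
  }
  json <- list(
    n_samples = report$summary$n,
    counts = report$summary$counts,
    options = report$options,
    scan = list(optimal_cutoff = report$scan$optimal_cutoff,
                optimal_p = report$scan$optimal_p,
                degenerate = report$scan$degenerate,
                n_candidates = nrow(report$scan$candidates),
                note = "minimal raw Fisher p over an exhaustive cutpoint scan; no multiplicity correction"),
    changepoint = list(
      split_vaf = report$changepoint$split_vaf,
      slope_difference = report$changepoint$slope_difference,
      low = unclass(report$changepoint$low_fit),
      high = unclass(report$changepoint$high_fit),
      candidates_evaluated = report$changepoint$candidates_evaluated),
    flags = list(n_flagged = sum(report$flags$flagged),
                 n_samples = nrow(report$flags))
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}
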