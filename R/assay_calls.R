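## MGMT promoter methylation call rules for the three assay families:
## pyrosequencing (mean-CpG percent threshold), methylation array
## (MGMT-STP27 logistic model on two CpG M-values), and ddPCR (percent
## threshold). All threshold comparisons are inclusive (>=).

#' Call MGMT promoter methylation from pyrosequencing site percents
#'
#' The pyrosequencing score is the arithmetic mean of the per-CpG percent
#' methylation values; the promoter is called methylated (POSITIVE) when the
#' score is greater than or equal to the cutoff. The conventional clinical
#' cutoff is 10%; 7.28% is the cutoff used in the original validation of the
#' MGMT-STP27 array model and is useful when comparing pyrosequencing with
#' array calls.
#'
#' @param site_percents Numeric vector of 1 to 8 per-CpG percent methylation
#'   values, each in \[0, 100\]. A single aggregate score may be passed as a
#'   length-1 vector.
#' @param cutoff Positivity cutoff in percent (default 10.0).
#' @return A `pyro_call` list: `score` (mean percent), `call`
#'   (`"POSITIVE"`/`"NEGATIVE"`), `cutoff_used`.
#' @export
#' @examples
#' call_pyro(c(12, 8, 11, 9))        # score 10, POSITIVE at the 10% cutoff
#' call_pyro(5.52)                   # NEGATIVE
#' call_pyro(5.52, cutoff = 7.28)    # still NEGATIVE
call_pyro <- function(site_percents, cutoff = 10.0) {
  if (length(site_percents) < 1 || length(site_percents) > 8) {
    stop_mgmtvaf("site_percents must contain 1 to 8 values",
                 "mgmtvaf_argument_error")
  }
  if (any(!is.finite(site_percents)) ||
      any(site_percents < 0 | site_percents > 100)) {
    stop_mgmtvaf("site percents must be finite and within [0, 100]",
                 "mgmtvaf_validation_error")
  }
  score <- mean(site_percents)
  structure(
    list(score = score,
         call = if (score >= cutoff) "POSITIVE" else "NEGATIVE",
         cutoff_used = cutoff),
    class = "pyro_call"
  )
}

#' @export
print.pyro_call <- function(x, ...) {
  cat(sprintf("MGMT pyrosequencing: score %.2f%% -> %s (cutoff %.2f%%)\n",
              x$score, x$call, x$cutoff_used))
  invisible(x)
}

#' MGMT-STP27 logistic model specification
#'
#' The MGMT-STP27 model predicts the probability that the MGMT promoter is
#' methylated from the M-values of two array CpG probes, cg12434587 and
#' cg12981137, via logistic regression. Coefficients are configurable; the
#' packaged defaults (`bady_model()` with no arguments) are the published
#' MGMT-STP27 estimates shipped in `inst/extdata/bady_stp27.json`.
#'
#' @param intercept,coef_cg12434587,coef_cg12981137 Logistic regression
#'   coefficients on the M-value scale.
#' @param prob_cutoff Probability above which (inclusive) the promoter is
#'   called methylated.
#' @param equivocal_halfwidth Half-width of the symmetric equivocal band
#'   around `prob_cutoff`; 0 (the default) yields binary calls.
#' @return A `bady_model` list.
#' @export
bady_model <- function(intercept = NULL, coef_cg12434587 = NULL,
                       coef_cg12981137 = NULL, prob_cutoff = NULL,
                       equivocal_halfwidth = NULL) {
  defaults <- jsonlite::read_json(
    system.file("extdata", "bady_stp27.json", package = "mgmtvaf"),
    simplifyVector = TRUE
  )
  m <- list(
    intercept = intercept %||% defaults$intercept,
    coef_cg12434587 = coef_cg12434587 %||% defaults$coef_cg12434587,
    coef_cg12981137 = coef_cg12981137 %||% defaults$coef_cg12981137,
    prob_cutoff = prob_cutoff %||% defaults$prob_cutoff,
    equivocal_halfwidth = equivocal_halfwidth %||% defaults$equivocal_halfwidth
  )
  validate_bady_model(m)
  structure(m, class = "bady_model")
}

#' Read an MGMT-STP27 model from a JSON config file
#'
#' @param path JSON file with fields `intercept`, `coef_cg12434587`,
#'   `coef_cg12981137`, `prob_cutoff`, `equivocal_halfwidth`.
#' @return A `bady_model`.
#' @export
read_bady_model <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bady_model(cfg$intercept, cfg$coef_cg12434587, cfg$coef_cg12981137,
             cfg$prob_cutoff, cfg$equivocal_halfwidth)
}

validate_bady_model <- function(m) {
  vals <- unlist(m[c("intercept", "coef_cg12434587", "coef_cg12981137",
                     "prob_cutoff", "equivocal_halfwidth")])
  if (length(vals) != 5 || any(!is.finite(vals))) {
    stop_mgmtvaf("bady_model requires five finite numeric fields",
                 "mgmtvaf_argument_error")
  }
  if (m$prob_cutoff <= 0 || m$prob_cutoff >= 1) {
    stop_mgmtvaf("prob_cutoff must lie strictly inside (0, 1)",
                 "mgmtvaf_argument_error")
  }
  if (m$equivocal_halfwidth < 0 ||
      m$equivocal_halfwidth >= min(m$prob_cutoff, 1 - m$prob_cutoff)) {
    stop_mgmtvaf("equivocal_halfwidth must be >= 0 and < min(cutoff, 1 - cutoff)",
                 "mgmtvaf_argument_error")
  }
  invisible(m)
}

#' Call MGMT promoter methylation from array M-values (MGMT-STP27)
#'
#' Evaluates the logistic model on the M-values of probes cg12434587 and
#' cg12981137. The MGMT score is the logit of the predicted probability
#' (i.e., the linear predictor). The call is POSITIVE when the probability is
#' at or above `prob_cutoff + equivocal_halfwidth`, NEGATIVE at or below
#' `prob_cutoff - equivocal_halfwidth`, and EQUIVOCAL in between.
#'
#' @param m1 M-value of cg12434587.
#' @param m2 M-value of cg12981137.
#' @param model A [bady_model()]; defaults to the packaged published model.
#' @return A `bady_result` list: `probability`, `logit_score`, `call`.
#' @export
#' @examples
#' call_bady(0, 0)        # probability determined by the intercept alone
#' call_bady(-5, -5)      # strongly unmethylated M-values
call_bady <- function(m1, m2, model = bady_model()) {
  if (!is.finite(m1) || !is.finite(m2)) {
    stop_mgmtvaf("M-values must be finite", "mgmtvaf_argument_error")
  }
  validate_bady_model(model)
  eta <- model$intercept + model$coef_cg12434587 * m1 +
    model$coef_cg12981137 * m2
  p <- stats::plogis(eta)
  hi <- model$prob_cutoff + model$equivocal_halfwidth
  lo <- model$prob_cutoff - model$equivocal_halfwidth
  call <- if (p >= hi) "POSITIVE" else if (p <= lo) "NEGATIVE" else "EQUIVOCAL"
  structure(list(probability = p, logit_score = eta, call = call),
            class = "bady_result")
}

#' @export
print.bady_result <- function(x, ...) {
  cat(sprintf("MGMT-STP27: P(methylated) = %.4f, score (logit) = %.3f -> %s\n",
              x$probability, x$logit_score, x$call))
  invisible(x)
}

#' Convert a methylation beta value to an M-value
#'
#' M = log2(beta / (1 - beta)): the logit (base 2) of the methylation
#' fraction. Defined only for beta strictly inside (0, 1).
#'
#' @param beta Methylation fraction(s) in (0, 1).
#' @return M-value(s).
#' @export
#' @examples
#' beta_to_m(0.5)  # 0
#' beta_to_m(0.8)  # 2
beta_to_m <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0 | beta >= 1)) {
    stop_mgmtvaf("beta must lie strictly inside (0, 1)", "mgmtvaf_domain_error")
  }
  log2(beta / (1 - beta))
}

#' Compute an M-value from methylated/unmethylated intensities
#'
#' Convenience helper `log2((meth + alpha) / (unmeth + alpha))` with the
#' customary offset `alpha = 1`. Raw intensities are not a required input
#' anywhere in the package; M-values or betas are the ingestion boundary.
#'
#' @param meth,unmeth Nonnegative intensities.
#' @param alpha Offset guarding against zero intensities (default 1).
#' @return M-value(s).
#' @export
m_from_intensities <- function(meth, unmeth, alpha = 1) {
  if (any(meth < 0) || any(unmeth < 0)) {
    stop_mgmtvaf("intensities must be nonnegative", "mgmtvaf_domain_error")
  }
  log2((meth + alpha) / (unmeth + alpha))
}

#' Call MGMT promoter methylation from a ddPCR percent measurement
#'
#' @param meth_percent Percent methylated template in \[0, 100\].
#' @param cutoff Positivity cutoff in percent (default 4.0).
#' @return `"POSITIVE"` if `meth_percent >= cutoff`, else `"NEGATIVE"`.
#' @export
#' @examples
#' call_ddpcr(8.8)  # POSITIVE
#' call_ddpcr(0)    # NEGATIVE
call_ddpcr <- function(meth_percent, cutoff = 4.0) {
  if (!is.finite(meth_percent) || meth_percent < 0 || meth_percent > 100) {
    stop_mgmtvaf("meth_percent must lie in [0, 100]", "mgmtvaf_validation_error")
  }
  if (meth_percent >= cutoff) "POSITIVE" else "NEGATIVE"
}
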