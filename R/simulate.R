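## Synthetic cohort generator built on the purity-dilution signal model: the
## observed bulk methylation signal is a tumor-fraction-weighted mixture of
## the tumor-cell signal and a non-neoplastic background signal, so
## paucicellular specimens of truly methylated tumors can fall below the
## positivity cutoff and read out as false negatives.

#' Simulation configuration for the dilution-model cohort generator
#'
#' Defaults emulate the structure of a consecutive adult-type diffuse glioma
#' cohort: subtype mix roughly 68% IDH-wildtype GBM / 21% IDH-mutant
#' astrocytoma / 11% oligodendroglioma, MGMT methylation prevalences of 0.35
#' / 0.70 / 0.96 respectively, and per-subtype driver VAF drawn as 0.5 times
#' a Beta variate calibrated to mean VAF about 0.34-0.39. Signal constants
#' (tumor methylated signal 30%, unmethylated 3%, non-neoplastic background
#' 2%, between-site SD 8, measurement SD 2) are the generator's own choices,
#' set so a truly methylated GBM crosses the 10% pyrosequencing cutoff at a
#' tumor fraction near 0.3-0.4 (driver VAF 0.15-0.2). They are synthetic
#' constants, not estimates of any real cohort.
#'
#' @param n Number of samples.
#' @param subtype_mix Named probabilities over the three subtypes, summing
#'   to 1.
#' @param prevalence_by_subtype Named per-subtype probability that the tumor
#'   is truly MGMT-methylated.
#' @param vaf_beta_params Named list of `c(alpha, beta)` shape pairs; VAF is
#'   drawn as `0.5 * rbeta(alpha, beta)`.
#' @param mu_meth,mu_unmeth Mean tumor-cell per-site percent signal when the
#'   tumor is truly methylated / unmethylated.
#' @param mu_background Mean non-neoplastic background percent signal.
#' @param sigma_signal SD of per-site tumor-cell signals.
#' @param sigma_noise SD of the per-site measurement noise, of the shared
#'   per-sample background draw, and of the microscopic-cellularity noise.
#' @param micro_bias_slope Overestimation (percentage points at zero purity)
#'   of microscopic cellularity relative to the true value; the bias decays
#'   linearly to 0 at full purity.
#' @param pyro_cutoff Pyrosequencing positivity cutoff in percent.
#' @param seed Integer seed; same config + seed reproduces the cohort
#'   bit-for-bit.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 500,
                       subtype_mix = c(GBM_IDHwt = 0.68, ASTRO_IDHmut = 0.21,
                                       OLIGO_IDHmut_codel = 0.11),
                       prevalence_by_subtype = c(GBM_IDHwt = 0.35,
                                                 ASTRO_IDHmut = 0.70,
                                                 OLIGO_IDHmut_codel = 0.96),
                       vaf_beta_params = list(GBM_IDHwt = c(3.4, 1.6),
                                              ASTRO_IDHmut = c(3.8, 1.2),
                                              OLIGO_IDHmut_codel = c(3.9, 1.1)),
                       mu_meth = 30, mu_unmeth = 3, mu_background = 2,
                       sigma_signal = 8, sigma_noise = 2,
                       micro_bias_slope = 30,
                       pyro_cutoff = 10, seed = 1L) {
  cfg <- list(n = as.integer(n), subtype_mix = subtype_mix,
              prevalence_by_subtype = prevalence_by_subtype,
              vaf_beta_params = vaf_beta_params,
              mu_meth = mu_meth, mu_unmeth = mu_unmeth,
              mu_background = mu_background,
              sigma_signal = sigma_signal, sigma_noise = sigma_noise,
              micro_bias_slope = micro_bias_slope,
              pyro_cutoff = pyro_cutoff, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n < 1) stop_mgmtvaf("n must be >= 1", "mgmtvaf_argument_error")
  mix <- cfg$subtype_mix
  if (!setequal(names(mix), SUBTYPES) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8) {
    stop_mgmtvaf("subtype_mix must be nonnegative over the three subtypes and sum to 1",
                 "mgmtvaf_argument_error")
  }
  prev <- cfg$prevalence_by_subtype
  if (!setequal(names(prev), SUBTYPES) || any(prev < 0 | prev > 1)) {
    stop_mgmtvaf("prevalence_by_subtype must be probabilities for all subtypes",
                 "mgmtvaf_argument_error")
  }
  if (!setequal(names(cfg$vaf_beta_params), SUBTYPES) ||
      any(vapply(cfg$vaf_beta_params,
                 function(p) length(p) != 2 || any(p <= 0), logical(1)))) {
    stop_mgmtvaf("vaf_beta_params needs a positive (alpha, beta) pair per subtype",
                 "mgmtvaf_argument_error")
  }
  if (cfg$sigma_signal < 0 || cfg$sigma_noise < 0) {
    stop_mgmtvaf("sigmas must be >= 0", "mgmtvaf_argument_error")
  }
  pcts <- base::c(cfg$mu_meth, cfg$mu_unmeth, cfg$mu_background, cfg$pyro_cutoff)
  if (any(!is.finite(pcts)) || any(pcts < 0 | pcts > 100)) {
    stop_mgmtvaf("signal means and cutoff must lie in [0, 100]",
                 "mgmtvaf_argument_error")
  }
  if (!(cfg$mu_background < cfg$pyro_cutoff && cfg$pyro_cutoff < cfg$mu_meth)) {
    stop_mgmtvaf("need mu_background < pyro_cutoff < mu_meth",
                 "mgmtvaf_argument_error")
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path Config file; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  if (!is.null(args$subtype_mix)) args$subtype_mix <- unlist(args$subtype_mix)
  if (!is.null(args$prevalence_by_subtype)) {
    args$prevalence_by_subtype <- unlist(args$prevalence_by_subtype)
  }
  if (!is.null(args$vaf_beta_params)) {
    args$vaf_beta_params <- lapply(args$vaf_beta_params, unlist)
  }
  do.call(sim_config, args)
}

#' Write a simulation configuration to YAML or JSON
#'
#' Serializes the config in the canonical form [read_sim_config()] expects:
#' named probability vectors become mappings (plain YAML serialization of
#' named atomic vectors would drop the names).
#'
#' @param config A `sim_config`.
#' @param path Output file; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  out <- unclass(config)
  out$subtype_mix <- as.list(out$subtype_mix)
  out$prevalence_by_subtype <- as.list(out$prevalence_by_subtype)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Expected observed signal under the purity-dilution mixture
#'
#' A bulk specimen with tumor fraction `f` mixes tumor-cell signal with
#' non-neoplastic background signal in proportion: the expected observed
#' percent is `f * s_tumor + (1 - f) * s_background`.
#'
#' @param f Tumor fraction(s) in \[0, 1\].
#' @param s_tumor Tumor-cell signal(s) in percent, \[0, 100\].
#' @param s_background Background signal(s) in percent, \[0, 100\].
#' @return Expected observed percent signal.
#' @export
#' @examples
#' expected_observed_score(0.5, 30, 2)  # 16
expected_observed_score <- function(f, s_tumor, s_background) {
  if (any(!is.finite(f)) || any(f < 0 | f > 1)) {
    stop_mgmtvaf("f must lie in [0, 1]", "mgmtvaf_domain_error")
  }
  if (any(s_tumor < 0 | s_tumor > 100) ||
      any(s_background < 0 | s_background > 100)) {
    stop_mgmtvaf("signals must lie in [0, 100]", "mgmtvaf_domain_error")
  }
  f * s_tumor + (1 - f) * s_background
}

#' Simulate a glioma cohort under the dilution model
#'
#' Per sample: draw subtype from the mix, true methylation status from the
#' subtype prevalence, and VAF as half a Beta variate; the tumor fraction is
#' `min(2 * VAF, 1)`. Four per-CpG tumor-cell signals are drawn normal
#' around `mu_meth` or `mu_unmeth` (SD `sigma_signal`, clamped to
#' \[0, 100\]); one shared background draw per sample (normal around
#' `mu_background`, SD `sigma_noise`, clamped) dilutes all four sites, so
#' sites correlate through purity. Observed site percents add measurement
#' noise (SD `sigma_noise`) and are clamped to \[0, 100\]; the
#' pyrosequencing score is their mean, called at `pyro_cutoff`. Microscopic
#' cellularity is the true percent cellularity plus a positive bias
#' `micro_bias_slope * (1 - f)` and noise, clamped to \[0, 100\].
#' Clamping (rather than resampling) slightly biases means near the scale
#' boundaries.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (a `glioma_cohort`; all samples PYRO) and
#'   `truth` (tibble of per-sample latent values: `true_methylated`,
#'   `tumor_fraction`, `true_site_signal` = mean undiluted site signal).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n
  withr_seed <- config$seed
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(withr_seed)

  subtype <- sample(SUBTYPES, n, replace = TRUE,
                    prob = config$subtype_mix[SUBTYPES])
  gene_pick <- stats::runif(n)  # IDH1 vs IDH2 split for IDH-mutant subtypes
  driver_gene <- ifelse(subtype == "GBM_IDHwt", "TERTp",
                        ifelse(gene_pick < 0.9, "IDH1", "IDH2"))
  vaf <- numeric(n)
  for (st in SUBTYPES) {
    idx <- subtype == st
    p <- config$vaf_beta_params[[st]]
    vaf[idx] <- 0.5 * stats::rbeta(sum(idx), p[1], p[2])
  }
  true_meth <- stats::runif(n) < config$prevalence_by_subtype[subtype]
  f <- pmin(2 * vaf, 1)

  mu_site <- ifelse(true_meth, config$mu_meth, config$mu_unmeth)
  sites_true <- matrix(stats::rnorm(4 * n, mean = rep(mu_site, each = 4),
                                    sd = config$sigma_signal),
                       nrow = 4)
  sites_true <- clamp(sites_true, 0, 100)
  background <- clamp(stats::rnorm(n, config$mu_background, config$sigma_noise),
                      0, 100)
  observed <- sweep(sites_true, 2, f, `*`) +
    matrix(rep((1 - f) * background, each = 4), nrow = 4) +
    matrix(stats::rnorm(4 * n, 0, config$sigma_noise), nrow = 4)
  observed <- clamp(observed, 0, 100)
  score <- colMeans(observed)
  call <- ifelse(score >= config$pyro_cutoff, "POSITIVE", "NEGATIVE")
  micro <- clamp(100 * f + config$micro_bias_slope * (1 - f) +
                   stats::rnorm(n, 0, config$sigma_noise), 0, 100)

  cohort <- tibble::tibble(
    sample_id = sprintf("SIM-%04d", seq_len(n)),
    subtype = subtype,
    driver_gene = driver_gene,
    driver_vaf = vaf,
    assay = "PYRO",
    mgmt_score = score,
    mgmt_call = call,
    site_p1 = observed[1, ], site_p2 = observed[2, ],
    site_p3 = observed[3, ], site_p4 = observed[4, ],
    micro_cellularity = micro
  )
  truth <- tibble::tibble(
    sample_id = cohort$sample_id,
    true_methylated = true_meth,
    tumor_fraction = f,
    true_site_signal = colMeans(sites_true)
  )
  provenance <- sprintf("simulate_cohort(n=%d, seed=%d)", n, config$seed)
  list(cohort = as_cohort(cohort, provenance = provenance), truth = truth)
}

#' Simulate a cohort with a sharp step change in positivity
#'
#' A deliberately simple generator used to benchmark cutpoint recovery: VAF
#' is uniform on (0, 0.5) and the probability of a POSITIVE call jumps from
#' `p_below` to `p_above` at `step_vaf`. Defaults (0.10 below, 0.60 above)
#' echo the contrast between paucicellular and cellular IDH-wildtype GBM.
#'
#' @param n Number of samples.
#' @param step_vaf True step location.
#' @param p_below,p_above Positivity probabilities below / at-or-above the
#'   step.
#' @param seed Integer seed.
#' @return A `glioma_cohort` (all GBM, PYRO, no scores).
#' @export
simulate_step_cohort <- function(n = 500, step_vaf = 0.2, p_below = 0.10,
                                 p_above = 0.60, seed = 1L) {
  if (step_vaf <= 0 || step_vaf >= 0.5) {
    stop_mgmtvaf("step_vaf must lie in (0, 0.5)", "mgmtvaf_argument_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  vaf <- stats::runif(n, 0, 0.5)
  p <- ifelse(vaf >= step_vaf, p_above, p_below)
  call <- ifelse(stats::runif(n) < p, "POSITIVE", "NEGATIVE")
  as_cohort(tibble::tibble(
    sample_id = sprintf("STEP-%04d", seq_len(n)),
    subtype = "GBM_IDHwt", driver_gene = "TERTp",
    driver_vaf = vaf, assay = "PYRO", mgmt_call = call
  ), provenance = sprintf("simulate_step_cohort(n=%d, seed=%d)", n, seed))
}

#' Piecewise-linear hinge curve fixture
#'
#' Builds the canonical changepoint test fixture: a curve rising with
#' `low_slope` up to the knee, flat at `plateau` beyond it, on a regular VAF
#' grid, with optional Gaussian noise. With `noise_sd = 0` the hinge is
#' exact and the knee is recovered exactly by [two_part_fit()].
#'
#' @param knee Knee location, strictly inside (0, 0.5).
#' @param low_slope Slope of the rising segment.
#' @param plateau Curve value at and beyond the knee.
#' @param grid_step VAF grid spacing; the grid runs from `grid_step` to 0.5.
#' @param noise_sd Gaussian noise SD (0 for the exact hinge).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A `cumulative_curve` (statistic `"MEAN_SCORE"`).
#' @export
make_hinge_curve <- function(knee, low_slope, plateau, grid_step = 0.02,
                             noise_sd = 0, seed = 1L) {
  if (knee <= 0 || knee >= 0.5) {
    stop_mgmtvaf("knee must lie in (0, 0.5)", "mgmtvaf_argument_error")
  }
  if (grid_step <= 0 || grid_step > knee) {
    stop_mgmtvaf("grid_step must be positive and no larger than the knee",
                 "mgmtvaf_argument_error")
  }
  # snap the grid so representable knees (0.2, 0.18, ...) compare exactly
  x <- round(seq(grid_step, 0.5, by = grid_step), 12)
  y <- ifelse(x <= knee, plateau + low_slope * (x - knee), plateau)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  cumulative_curve(x, y, statistic = "MEAN_SCORE")
}
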