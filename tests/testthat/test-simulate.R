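test_that("expected_observed_score is the purity-weighted mixture", {
  expect_equal(expected_observed_score(1, 30, 2), 30)
  expect_equal(expected_observed_score(0, 30, 2), 2)
  expect_equal(expected_observed_score(0.5, 30, 2), 16)
  expect_error(expected_observed_score(1.2, 30, 2), class = "mgmtvaf_domain_error")
  expect_error(expected_observed_score(0.5, 130, 2), class = "mgmtvaf_domain_error")
})

test_that("sim_config validates its fields before any sampling", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n = 0), class = "mgmtvaf_argument_error")
  expect_error(sim_config(subtype_mix = c(GBM_IDHwt = 1)),
               class = "mgmtvaf_argument_error")
  expect_error(sim_config(mu_background = 15),  # violates background < cutoff
               class = "mgmtvaf_argument_error")
  expect_error(sim_config(sigma_noise = -1), class = "mgmtvaf_argument_error")
})

test_that("same config and seed reproduce the cohort bit-for-bit", {
  cfg <- sim_config(n = 150, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sim_config(n = 150, seed = 43))
  expect_false(identical(a$cohort$driver_vaf, c2$cohort$driver_vaf))
})

test_that("noise-free limits behave as the dilution arithmetic dictates", {
  # full methylation, no noise, VAF pinned at 0.5 -> every score is mu_meth
  cfg <- sim_config(
    n = 50,
    prevalence_by_subtype = c(GBM_IDHwt = 1, ASTRO_IDHmut = 1,
                              OLIGO_IDHmut_codel = 1),
    vaf_beta_params = list(GBM_IDHwt = c(1e6, 1), ASTRO_IDHmut = c(1e6, 1),
                           OLIGO_IDHmut_codel = c(1e6, 1)),
    mu_meth = 30, mu_background = 2, sigma_signal = 0, sigma_noise = 0,
    seed = 1
  )
  sim <- simulate_cohort(cfg)
  expect_true(all(abs(sim$cohort$mgmt_score - 30) < 1e-3))
  expect_true(all(sim$cohort$mgmt_call == "POSITIVE"))

  # no methylation anywhere -> nothing crosses the 10% cutoff
  cfg0 <- sim_config(
    n = 50,
    prevalence_by_subtype = c(GBM_IDHwt = 0, ASTRO_IDHmut = 0,
                              OLIGO_IDHmut_codel = 0),
    mu_unmeth = 3, mu_background = 2, sigma_signal = 0.5, sigma_noise = 0.5,
    seed = 2
  )
  expect_true(all(simulate_cohort(cfg0)$cohort$mgmt_call == "NEGATIVE"))
})

test_that("marginal positivity approaches the analytic noise-free value", {
  # noise-free: a truly methylated sample is positive iff
  # f * mu_meth + (1 - f) * mu_background >= cutoff, i.e. VAF >= v*;
  # unmethylated samples never cross. Marginal rate =
  # prevalence * P(VAF >= v*) under the Beta VAF law.
  cfg <- sim_config(n = 5000, sigma_signal = 0, sigma_noise = 0, seed = 7,
                    subtype_mix = c(GBM_IDHwt = 1, ASTRO_IDHmut = 0,
                                    OLIGO_IDHmut_codel = 0))
  sim <- simulate_cohort(cfg)
  v_star <- (cfg$pyro_cutoff - cfg$mu_background) /
    (2 * (cfg$mu_meth - cfg$mu_background))
  shape <- cfg$vaf_beta_params$GBM_IDHwt
  expected <- cfg$prevalence_by_subtype[["GBM_IDHwt"]] *
    stats::pbeta(2 * v_star, shape[1], shape[2], lower.tail = FALSE)
  observed <- mean(sim$cohort$mgmt_call == "POSITIVE")
  se <- sqrt(expected * (1 - expected) / cfg$n)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("false negatives concentrate at low VAF among truly methylated tumors", {
  rates <- matrix(NA_real_, nrow = 20, ncol = 5)
  for (seed in 1:20) {
    sim <- simulate_cohort(sim_config(n = 1000, seed = seed))
    meth <- sim$truth$true_methylated
    fn <- meth & sim$cohort$mgmt_call == "NEGATIVE"
    qs <- cut(sim$cohort$driver_vaf,
              quantile(sim$cohort$driver_vaf, probs = seq(0, 1, 0.2)),
              include.lowest = TRUE, labels = FALSE)
    rates[seed, ] <- vapply(1:5, function(q) {
      sum(fn[qs == q]) / sum(meth[qs == q])
    }, numeric(1))
  }
  pooled <- colMeans(rates)
  # pooled FN rate nonincreasing across VAF quintiles
  expect_true(all(diff(pooled) <= 0))
  # and the extremes are far apart (paucicellular samples dominate the risk)
  expect_gt(pooled[1], pooled[5] + 0.1)
})

test_that("microscopic cellularity is overestimated at low purity", {
  sim <- simulate_cohort(sim_config(n = 2000, seed = 11))
  delta <- sim$cohort$micro_cellularity - 100 * sim$truth$tumor_fraction
  low_f <- sim$truth$tumor_fraction < 0.3
  expect_gt(mean(delta[low_f]), 0)
  # direction check mirrored through the discrepancy regression
  res <- cellularity_discrepancy(sim$cohort)
  expect_lt(res$fit$slope, 0)
})

test_that("the step cohort has its positivity step where requested", {
  co <- simulate_step_cohort(n = 4000, step_vaf = 0.2, seed = 5)
  below <- co$driver_vaf < 0.2
  expect_equal(mean(co$mgmt_call[below] == "POSITIVE"), 0.10, tolerance = 0.25)
  expect_equal(mean(co$mgmt_call[!below] == "POSITIVE"), 0.60, tolerance = 0.1)
  expect_identical(as.data.frame(simulate_step_cohort(n = 100, seed = 9)),
                   as.data.frame(simulate_step_cohort(n = 100, seed = 9)))
  expect_error(simulate_step_cohort(step_vaf = 0.7),
               class = "mgmtvaf_argument_error")
})

test_that("hinge helper is deterministic and validates geometry", {
  a <- make_hinge_curve(0.2, 1, 0.2, noise_sd = 0.02, seed = 3)
  b <- make_hinge_curve(0.2, 1, 0.2, noise_sd = 0.02, seed = 3)
  expect_identical(a$value, b$value)

  flat <- make_hinge_curve(0.2, 0, 0.3)
  expect_true(all(flat$value == 0.3))

  expect_error(make_hinge_curve(0.6, 1, 0.2), class = "mgmtvaf_argument_error")
  expect_error(make_hinge_curve(0.2, 1, 0.2, grid_step = 0.3),
               class = "mgmtvaf_argument_error")
})

test_that("sim configs round-trip through YAML and JSON files", {
  cfg <- sim_config(n = 77, seed = 3, mu_meth = 28)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, ypath)
  expect_equal(read_sim_config(ypath)$mu_meth, 28)
  expect_equal(read_sim_config(ypath)$n, 77L)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, jpath)
  cfg2 <- read_sim_config(jpath)
  expect_equal(cfg2$vaf_beta_params, cfg$vaf_beta_params)
  expect_identical(as.data.frame(simulate_cohort(cfg2)$cohort),
                   as.data.frame(simulate_cohort(cfg)$cohort))
})
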