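test_that("fisher_exact reproduces printed contingency-table p-values", {
  tabs <- results_2x2()$tables
  expect_lt(fisher_exact(tabs$pooled_pyro_vaf_0325$counts)$p_value, 0.0001)
  expect_equal(round(fisher_exact(tabs$gbm_array_vs_pyro_cut10$counts)$p_value, 3),
               0.004)
  expect_equal(round(fisher_exact(tabs$gbm_pyro_cut728_vs_array$counts)$p_value, 3),
               0.097)
  expect_equal(round(fisher_exact(tabs$gbm_lowvaf_pyro_vs_array$counts)$p_value, 3),
               0.039)
  expect_equal(round(fisher_exact(tabs$gbm_highvaf_pyro_vs_array$counts)$p_value, 3),
               0.639)
})

test_that("fisher_exact handles symmetric, degenerate and infinite-OR tables", {
  sym <- fisher_exact(1, 1, 1, 1)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$odds_ratio, 1)

  expect_error(fisher_exact(0, 0, 0, 0), class = "mgmtvaf_argument_error")
  expect_error(fisher_exact(1, 2, 3), class = "mgmtvaf_argument_error")
  expect_error(fisher_exact(1.5, 2, 3, 4), class = "mgmtvaf_argument_error")

  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
  # matrix and vector forms agree with the four-scalar form
  m <- matrix(c(7, 3, 2, 8), 2, 2, byrow = TRUE)
  expect_equal(fisher_exact(m), fisher_exact(7, 3, 2, 8))
  expect_equal(fisher_exact(c(7, 3, 2, 8)), fisher_exact(7, 3, 2, 8))
})

test_that("fisher_exact equals brute-force enumeration on all small tables", {
  # exhaustive hypergeometric oracle over random tables with n <= 20
  set.seed(101)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(1:20, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p_value
    want <- fisher_p_bruteforce(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("fisher_exact agrees with stats::fisher.test and is swap-invariant", {
  set.seed(202)
  for (i in 1:50) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p_value
    ref <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-10)
    expect_true(got > 0 && got <= 1)
    # simultaneous row swap + column swap leaves the table's p unchanged
    swapped <- fisher_exact(cells[4], cells[3], cells[2], cells[1])$p_value
    expect_equal(got, swapped, tolerance = 1e-12)
  }
})

test_that("the cutpoint scan finds the perfect-separation midpoint", {
  vaf <- c(0.05, 0.08, 0.11, 0.14, 0.17, 0.23, 0.28, 0.33, 0.38, 0.43)
  co <- tibble::tibble(
    sample_id = sprintf("P%02d", 1:10),
    subtype = "GBM_IDHwt", driver_gene = "TERTp",
    driver_vaf = vaf, assay = "PYRO",
    mgmt_call = rep(c("NEGATIVE", "POSITIVE"), each = 5)
  )
  scan <- scan_vaf_cutoffs(co, min_per_side = 2)
  expect_equal(scan$optimal_cutoff, (0.17 + 0.23) / 2)
  expect_equal(scan$optimal_p, fisher_exact(5, 0, 0, 5)$p_value)
  expect_false(scan$degenerate)
  # argmin property: the optimal p is minimal over all candidates
  expect_true(all(scan$optimal_p <= scan$candidates$p_value))
  # candidate guard: every candidate leaves min_per_side on each side
  expect_true(all(scan$candidates$n_above >= 2 & scan$candidates$n_below >= 2))
})

test_that("scan matches a brute-force midpoint scan on random cohorts", {
  co <- random_cohort(40, seed = 31)
  scan <- scan_vaf_cutoffs(co, min_per_side = 5)
  vaf <- sort(co$driver_vaf)
  mids <- (head(unique(vaf), -1) + tail(unique(vaf), -1)) / 2
  brute <- vapply(mids, function(cut) {
    above <- co$driver_vaf >= cut
    if (sum(above) < 5 || sum(!above) < 5) return(NA_real_)
    fisher_exact(sum(above & co$mgmt_call == "POSITIVE"),
                 sum(above & co$mgmt_call == "NEGATIVE"),
                 sum(!above & co$mgmt_call == "POSITIVE"),
                 sum(!above & co$mgmt_call == "NEGATIVE"))$p_value
  }, numeric(1))
  expect_equal(scan$candidates$p_value, brute[!is.na(brute)])
  expect_equal(scan$optimal_cutoff, mids[which.min(brute)])
  # bit-for-bit reproducible: no randomness in the scan
  expect_identical(scan$candidates, scan_vaf_cutoffs(co, min_per_side = 5)$candidates)
})

test_that("degenerate cohorts flag and guard conditions error", {
  co <- random_cohort(16, seed = 3)
  co$mgmt_call <- "POSITIVE"
  scan <- scan_vaf_cutoffs(co)
  expect_true(scan$degenerate)
  expect_equal(scan$optimal_p, 1)

  expect_error(scan_vaf_cutoffs(random_cohort(6)), class = "mgmtvaf_argument_error")
})

test_that("two-group comparisons match oracle computations", {
  expect_equal(compare_groups(rep(5, 4), rep(5, 4), "t_test"), 1)

  # U statistic equals pairwise wins + half-ties; cross-check p via wilcox
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 2.8)
  y <- c(0.8, 2.2, 1.9, 3.0, 2.5, 1.1)
  u_pairwise <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(suppressWarnings(stats::wilcox.test(x, y)$statistic)),
               u_pairwise)
  expect_equal(compare_groups(x, y, "mann_whitney"),
               suppressWarnings(stats::wilcox.test(x, y)$p.value))

  # a +100 shift at n = 10 is decisive for both methods
  set.seed(55)
  base_g <- rnorm(10)
  expect_lt(compare_groups(base_g + 100, base_g, "t_test"), 0.01)
  expect_lt(compare_groups(base_g + 100, base_g, "mann_whitney"), 0.01)

  expect_error(compare_groups(numeric(0), 1:3), class = "mgmtvaf_argument_error")
  expect_error(compare_groups(1, 1:3), class = "mgmtvaf_argument_error")
})
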