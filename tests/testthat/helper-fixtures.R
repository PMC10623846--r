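# Shared fixture builders. The re-tested GBM cohort and the printed 2x2
# tables ship as plain-text fixtures in inst/extdata; random cohorts are
# generated in code.

table3_cohort <- function() {
  read_cohort(system.file("extdata", "retest_table3.tsv", package = "mgmtvaf"))
}

results_2x2 <- function() {
  jsonlite::read_json(
    system.file("extdata", "results_2x2.json", package = "mgmtvaf"),
    simplifyVector = TRUE
  )
}

# A small valid cohort exercising every optional column, including blanks.
random_cohort <- function(n = 20, seed = 42) {
  set.seed(seed)
  subtype <- sample(c("GBM_IDHwt", "ASTRO_IDHmut", "OLIGO_IDHmut_codel"),
                    n, replace = TRUE)
  gene <- ifelse(subtype == "GBM_IDHwt", "TERTp",
                 sample(c("IDH1", "IDH2"), n, replace = TRUE))
  sites <- matrix(round(runif(4 * n, 0, 40), 2), ncol = 4)
  score <- rowMeans(sites)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    subtype = subtype,
    driver_gene = gene,
    driver_vaf = round(runif(n, 0.01, 0.6), 3),
    assay = "PYRO",
    mgmt_score = score,
    mgmt_call = ifelse(score >= 10, "POSITIVE", "NEGATIVE"),
    site_p1 = sites[, 1], site_p2 = sites[, 2],
    site_p3 = sites[, 3], site_p4 = sites[, 4],
    micro_cellularity = ifelse(seq_len(n) %% 3 == 0, NA,
                               round(runif(n, 5, 95), 1)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = sample(20:85, n, replace = TRUE)
  )
}

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum the probabilities of those no more probable than observed.
fisher_p_bruteforce <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c; total <- row1 + row2
  p_table <- function(x) {
    # hypergeometric probability from factorials, computed directly
    exp(lfactorial(row1) + lfactorial(row2) + lfactorial(col1) +
          lfactorial(total - col1) - lfactorial(total) -
          lfactorial(x) - lfactorial(row1 - x) - lfactorial(col1 - x) -
          lfactorial(row2 - col1 + x))
  }
  support <- max(0, col1 - row2):min(col1, row1)
  probs <- vapply(support, p_table, numeric(1))
  obs <- p_table(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
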