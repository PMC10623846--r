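test_that("read_cohort parses the re-tested GBM fixture with row-level validation", {
  co <- table3_cohort()
  expect_s3_class(co, "glioma_cohort")
  expect_equal(nrow(co), 12)

  # the VAF-0.10 sample scoring 11.06% is consistent with the 10.0% cutoff
  s5 <- co[co$sample_id == "Pyro-081", ]
  expect_equal(s5$driver_vaf, 0.10)
  expect_equal(s5$mgmt_score, 11.06)
  expect_identical(s5$mgmt_call, "POSITIVE")
  expect_identical(call_pyro(s5$mgmt_score)$call, s5$mgmt_call)
})

test_that("header-only files give an empty cohort and writes round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tsubtype\tdriver_vaf\tassay\tmgmt_call", path)
  empty <- read_cohort(path)
  expect_equal(nrow(empty), 0)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(empty, out)
  expect_equal(nrow(read_cohort(out)), 0)

  # non-trivial table round-trips exactly, blanks staying blank
  co <- as_cohort(random_cohort(15))
  write_cohort(co, out)
  back <- read_cohort(out)
  expect_equal(as.data.frame(back)[COHORT_NAMES <- names(co)],
               as.data.frame(co)[COHORT_NAMES])
  expect_true(any(is.na(back$micro_cellularity)))
  raw <- readLines(out)
  expect_false(any(grepl("\tNA(\t|$)", raw)))  # missing written as blank
})

test_that("delimiter auto-detection accepts comma files and enum case folding", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,subtype,driver_vaf,assay,mgmt_call",
    "x1,gbm_idhwt,0.2,pyro,positive"
  ), path)
  co <- read_cohort(path)
  expect_identical(co$subtype, "GBM_IDHwt")
  expect_identical(co$assay, "PYRO")
  expect_identical(co$mgmt_call, "POSITIVE")
})

test_that("schema and validation errors carry row diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tsubtype\tdriver_vaf", path)  # missing assay, call
  expect_error(read_cohort(path), class = "mgmtvaf_schema_error")

  bad_vaf <- random_cohort(4)
  bad_vaf$driver_vaf[3] <- 1.7
  err <- expect_error(as_cohort(bad_vaf), class = "mgmtvaf_validation_error")
  expect_match(conditionMessage(err), "row\\(s\\) 3")
  expect_match(conditionMessage(err), "driver_vaf")

  bad_enum <- random_cohort(3)
  bad_enum$mgmt_call[2] <- "MAYBE"
  expect_error(as_cohort(bad_enum), class = "mgmtvaf_validation_error")

  dup <- random_cohort(3)
  dup$sample_id[2] <- dup$sample_id[1]
  expect_error(as_cohort(dup), class = "mgmtvaf_validation_error")

  # score/site-mean consistency and subtype/driver-gene coupling
  inconsistent <- random_cohort(3)
  inconsistent$mgmt_score[1] <- inconsistent$mgmt_score[1] + 5
  expect_error(as_cohort(inconsistent), class = "mgmtvaf_validation_error")

  wrong_gene <- random_cohort(3)
  wrong_gene$subtype[1] <- "GBM_IDHwt"
  wrong_gene$driver_gene[1] <- "IDH1"
  expect_error(as_cohort(wrong_gene), class = "mgmtvaf_validation_error")
})

test_that("summarize_cohort reproduces hand-enumerated statistics", {
  s <- summarize_cohort(table3_cohort())
  expect_equal(unname(s$counts$sex[c("M", "F")]), c(4L, 8L))
  # sorted VAFs 0.02,0.02,0.04,0.07,0.10,0.10,0.25,0.28,0.35,0.44,0.49,0.78
  expect_equal(s$vaf_overall$median, 0.175)
  expect_equal(s$vaf_overall$min, 0.02)
  expect_equal(s$vaf_overall$max, 0.78)

  one <- summarize_cohort(random_cohort(5)[3, ])
  expect_equal(one$vaf_overall$mean, one$vaf_overall$median)
  expect_equal(one$vaf_overall$min, one$vaf_overall$max)

  two <- random_cohort(2)
  two$driver_vaf <- c(0.2, 0.4)
  expect_equal(summarize_cohort(two)$vaf_overall$median, 0.3)

  empty <- summarize_cohort(as_cohort(random_cohort(3)[0, ]))
  expect_equal(empty$n, 0L)
})

test_that("summary counts partition the cohort and QNS is excluded from VAF stats", {
  co <- random_cohort(30, seed = 9)
  co$mgmt_call[1:4] <- "QNS"
  s <- summarize_cohort(co)
  expect_equal(sum(s$counts$subtype), 30L)
  expect_equal(sum(s$counts$mgmt_call), 30L)  # QNS retained in the call table
  expect_equal(s$vaf_overall$n, 26L)          # ... but not in statistics
  expect_true(all(s$vaf$min <= s$vaf$median & s$vaf$median <= s$vaf$max))

  json <- summary_to_json(s)
  expect_true(jsonlite::validate(json))
})

test_that("round-trip identity holds across randomly generated tables", {
  for (seed in c(1, 2, 3)) {
    co <- as_cohort(random_cohort(12, seed = seed))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_cohort(co, path)
    back <- read_cohort(path)
    expect_equal(as.data.frame(back)[names(co)], as.data.frame(co)[names(co)])
  }
})
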