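Package: mgmtvaf
Title: Driver-Mutation VAF as a Quality-Assurance Metric for MGMT
    Promoter Methylation Testing in Diffuse Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the reliability of MGMT promoter
    methylation test results in adult-type diffuse glioma using the variant
    allelic frequency (VAF) of clonal driver mutations (TERT promoter,
    IDH1/IDH2) as a tumor-purity proxy. Implements the three common assay
    call rules (pyrosequencing mean-CpG threshold, the MGMT-STP27 logistic
    model for methylation arrays, and a droplet digital PCR threshold),
    VAF-ranked cumulative positivity and score curves, exhaustive
    Fisher-exact VAF cutpoint scanning, two-segment linear-regression
    changepoint detection on cumulative curves, VAF-based cellularity
    estimation and comparison against microscopic estimates, flagging of
    samples at risk of false-negative methylation calls, and a synthetic
    cohort generator built on a purity-dilution signal model so every
    pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
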