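---
title: "VAF-based quality assurance of MGMT methylation calls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VAF-based quality assurance of MGMT methylation calls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmtvaf)
```

## The dilution model

Every bulk methylation assay on an infiltrative glioma measures a mixture
of neoplastic and non-neoplastic DNA. *MGMT* promoter methylation is
restricted to tumor cells, so the expected observed signal of a specimen
with tumor-cell fraction $f$ is

$$ s_\mathrm{obs} = f \, s_\mathrm{tumor} + (1 - f)\, s_\mathrm{background}, $$

implemented by `expected_observed_score()`. For a clonal heterozygous,
copy-number-stable driver mutation (a *TERT* promoter mutation in
IDH-wildtype glioblastoma, *IDH1*/*IDH2* in the IDH-mutant subtypes),
each tumor cell carries one mutant allele, so $f \approx 2\cdot
\mathrm{VAF}$ and `cellularity_from_vaf()` reports
$\min(2\cdot\mathrm{VAF}\cdot 100\%, 100\%)$. Both relations assume
clonality, heterozygosity and copy-number neutrality at the driver locus;
they fail for subclonal drivers, loss of heterozygosity, or amplification,
which is why the package treats VAF-based cellularity as a QC covariate,
not ground truth.

A truly methylated tumor reads out negative whenever
$s_\mathrm{obs}$ falls below the assay cutoff — the false-negative
mechanism this package is built to expose. Solving the mixture for the
pyrosequencing cutoff $c$ gives the critical fraction
$f^* = (c - s_\mathrm{background}) / (s_\mathrm{tumor} -
s_\mathrm{background})$; with the package's default synthetic signal
constants (tumor 30%, background 2%, cutoff 10%) this is $f^* = 8/28
\approx 0.29$, i.e. a critical VAF near 0.14.

## Assay call rules

All threshold comparisons are inclusive (`>=`).

* **Pyrosequencing** (`call_pyro()`): score = arithmetic mean of the
  per-CpG percent methylation values (1–8 sites accepted; the clinical
  assay uses 4). Positive at score ≥ 10.0% by default; 7.28% is provided
  because the original validation of the array model used that cutoff,
  and comparisons between platforms should be run at both. Whether the
  clinical score is the mean or another aggregate is an assumption; the
  mean is the common convention and is validated against the per-site
  columns on ingestion (tolerance 0.01 percentage points).
* **Methylation array** (`call_bady()`): the MGMT-STP27 logistic model on
  the M-values of probes cg12434587 and cg12981137,
  $\operatorname{logit} P = \alpha + \beta_1 M_1 + \beta_2 M_2$. The
  packaged coefficients (α = 4.3215, β₁ = 0.5271, β₂ = 0.9265, cutoff
  P ≥ 0.358) are the published estimates, shipped as a versioned JSON
  config (`inst/extdata/bady_stp27.json`) rather than hard-coded, so a
  laboratory can substitute its own refit. The *MGMT* score is the logit
  of the predicted probability. An equivocal band of configurable
  half-width around the cutoff yields three-way calls; the default
  half-width is 0 (binary) because no published criterion defines the
  equivocal zone.
* **ddPCR** (`call_ddpcr()`): positive at ≥ 4.0% methylated template.

`beta_to_m()` converts methylation fractions to M-values,
$M = \log_2\big(\beta/(1-\beta)\big)$; `m_from_intensities()` offers the
customary $\log_2((\mathrm{meth}+1)/(\mathrm{unmeth}+1))$ helper, but
M-values or betas are the package's ingestion boundary — no IDAT or
vendor-file parsing.

## Cohort tables

Cohorts are plain delimited text (tab or comma, auto-detected from the
header; UTF-8; decimal points). Mandatory columns: `sample_id`,
`subtype`, `driver_vaf`, `assay`, `mgmt_call`. Enum tokens are matched
case-insensitively and written canonically; missing optional values are
empty strings, never zeros, and are never imputed. Validation is strict
and row-addressed: a VAF outside [0, 1], an unknown token, a duplicated
id, a pyrosequencing score inconsistent with its site percents, or a
subtype/driver-gene mismatch (IDH-wildtype GBM must carry `TERTp`;
IDH-mutant subtypes `IDH1`/`IDH2`) aborts the read naming the offending
rows. Samples called `QNS` (quantity not sufficient) are retained in the
table but excluded from every downstream statistic.

## Cumulative curves

`cumulative_positivity()` and `cumulative_score()` rank samples by
increasing VAF and compute the running mean positivity, or running
mean/median score, over each prefix. These curves make the dilution
effect visible as a depressed low-VAF limb. Choices worth knowing:

* **Ties.** The sort is stable on (VAF, `sample_id`). Permuting samples
  that share a VAF changes interior values within the tie block; only the
  block-final point is order-invariant, and curves should be read at
  block boundaries.
* **Running medians** over even-length prefixes use the midpoint of the
  two middle values.
* **Equivocal/QNS calls** are excluded (with a warning) rather than
  folded into negative: folding would manufacture dilution signal out of
  assay indeterminacy.

## Fisher-exact cutpoint scanning

`scan_vaf_cutoffs()` dichotomizes the cohort at every midpoint between
consecutive distinct VAFs (midpoints make the ≥/< assignment
unambiguous), builds the 2×2 table of group × call, and computes the
two-sided Fisher exact $p$ by hypergeometric probability-mass summation
(`fisher_exact()`, masses compared with a relative tolerance of
$10^{-7}$; the odds ratio is the sample estimate $ad/bc$, infinite when
$bc = 0$). The optimal cutpoint minimizes $p$; ties break toward the
smaller cutpoint. Candidates leaving fewer than `min_per_side` samples
(default 5) on either side are skipped to avoid degenerate tables.

The minimal $p$ is an *optimistically selected* statistic — several
hundred correlated tests are scanned and no multiplicity correction is
applied, because the scan is a localization device, not a hypothesis
test. Every output (print method, TSV, JSON) carries that caveat.

`compare_groups()` supplies the two-group comparisons used alongside the
scan: Student's t-test (unpaired, equal variances) and the Mann-Whitney
U / Wilcoxon rank-sum test. The Wilcoxon path follows R's convention of
exact $p$-values for small untied samples and the tie-corrected normal
approximation otherwise.

## Two-segment changepoint regression

`two_part_fit()` evaluates every candidate split of a cumulative curve:
the low segment is every point with VAF ≤ split, the high segment every
point with VAF ≥ split — the split point belongs to both, so the two OLS
lines describe the curve on either side of a shared knee (the standard
two-phase-regression convention; with a half-open assignment the exact
hinge has two tied maximizers and the knee is not identifiable). The
winning split maximizes the *signed* slope difference
$M_\mathrm{low} - M_\mathrm{high}$, ties toward the smaller split.
`enumerate_splits()` exposes the full candidate table; the winner is its
argmax by construction, which the tests assert as an oracle equivalence.

Segment fits use closed-form OLS (`fit_line()`), with $R^2 = 0$ defined
for a constant response (zero total sum of squares: no variance to
explain) and the slope $p$-value from the $t$ distribution on $n-2$
degrees of freedom.

**Choosing `min_seg`.** The default minimum segment size is 3, the
smallest for which slope, $R^2$ and the slope test are all defined. That
default is adequate for what the method is designed for — cumulative
curves, whose running statistics are heavily smoothed — but even there
the *first few prefix points* are means of 2–5 samples and jump by tens
of percentage points, and on curves with independent per-point noise the
problem is acute: the OLS slope of a $k$-point segment on a grid of step
$\Delta$ has standard deviation

$$ \sigma_\mathrm{slope} \approx \frac{\sigma}{\Delta}
   \sqrt{\frac{12}{k^3}}, $$

so with $k = 3$, $\Delta = 0.0025$ and $\sigma = 0.02$ a spurious edge
slope of magnitude ~6 is routine while a realistic hinge signal is ~1.
The slope-difference maximum is then captured by a random edge segment.
For such curves `min_seg` should scale with the curve: requiring each
segment to hold about a quarter of the points (in the spirit of the
15–25% trimming conventions of structural-break regression) keeps the
spurious term well below the signal. The recovery tests use
`min_seg = n/4` on 200-point noisy hinges for exactly this reason. A
large *default* trim would be wrong for the package's real use, where
the scientifically interesting knee sits in the low-VAF tail (around the
15th percentile of samples in a typical glioblastoma cohort) and must
remain admissible; hence the conservative default plus this guidance.

Numerical detail: `make_hinge_curve()` snaps its VAF grid with
`round(x, 12)` so that representable knees (0.2, 0.18, …) compare exactly
against the accumulated floating-point error of `seq()`; without the
snap, the "flat" segment of an exact hinge carries $10^{-17}$-scale
jitter and its fitted slope and $R^2$ are noise.

## Risk flagging and the false-negative rate

`flag_false_negative_risk()` flags samples whose call is NEGATIVE and
whose driver VAF lies below the subtype reliability cutoff, recommending
orthogonal re-testing (array or ddPCR) for flagged samples. Two cutoff
sets ship: the regression-derived set (GBM 0.18, astrocytoma 0.325,
oligodendroglioma 0.30, the default) and the Fisher-scan-derived set
(0.115 / 0.325 / 0.405); output always names the set used.
`estimate_fn_rate()` is the back-of-envelope cohort rate: (fraction of
samples below the cutoff) × (expected methylation prevalence), reported
as a proportion and as a percent to one decimal.

`run_report()` chains summary → curves → scan → changepoint → flags and
writes a JSON + TSV bundle containing no timestamps, so a rerun on the
same inputs is byte-identical — a deliberate property, asserted in the
tests, that makes report bundles diffable and cacheable.

## The synthetic cohort generator

`simulate_cohort()` exists so every pipeline stage has a truth-labeled
input; its defaults describe a plausible consecutive adult glioma cohort,
not any real dataset:

| parameter | default | meaning |
|---|---|---|
| `subtype_mix` | 0.68 / 0.21 / 0.11 | GBM / astrocytoma / oligodendroglioma mix of a consecutive cohort |
| `prevalence_by_subtype` | 0.35 / 0.70 / 0.96 | probability the tumor is truly methylated |
| `vaf_beta_params` | (3.4, 1.6), (3.8, 1.2), (3.9, 1.1) | VAF = 0.5·Beta(α, β); means ≈ 0.34 / 0.38 / 0.39 |
| `mu_meth`, `mu_unmeth` | 30, 3 (%) | tumor-cell per-site signal |
| `mu_background` | 2 (%) | non-neoplastic background signal |
| `sigma_signal` | 8 (%) | between-site biological spread |
| `sigma_noise` | 2 (%) | measurement noise, background spread, microscopy noise |
| `micro_bias_slope` | 30 (pp) | microscopy overestimation at zero purity, decaying linearly to 0 at full purity |
| `pyro_cutoff` | 10 (%) | positivity threshold |

Per sample: subtype, true methylation status, and VAF are drawn; four
per-CpG tumor signals (normal, clamped to [0, 100]) are diluted by one
*shared* background draw — sites correlate through purity, as they do in
tissue — and measurement noise is added before clamping again. The
signal constants were chosen once so that a truly methylated tumor
crosses the 10% cutoff near $f \approx 0.3$–0.4 (VAF 0.15–0.20), placing
the simulated positivity knee where the dilution mechanism predicts.
Clamping (rather than resampling) truncates the Gaussian tails and
slightly biases means near the scale boundaries; this is documented
rather than corrected because the bias is far below `sigma_signal`.

What the generator deliberately does **not** model: array intensity data
(the array arm exists only at the call level), intratumoral methylation
heterogeneity, subclonal or copy-number-altered drivers, and any
dependence of methylation prevalence on VAF. Passing tests therefore
demonstrate that the pipeline recovers structure *under the dilution
model's own assumptions* — they are evidence of internal correctness,
not of clinical performance on real cohorts.

`simulate_step_cohort()` is a simpler benchmark generator (uniform VAF,
positivity jumping from 0.10 to 0.60 at a chosen VAF — rates echoing the
contrast between paucicellular and cellular glioblastoma) used to test
cutpoint-scan localization. `make_hinge_curve()` provides the
changepoint fixture.

## Problem sizes and runtime

The test suite and the acceptance script are sized for interactive use:
oracle equivalences run on a few hundred random 2×2 tables (n ≤ 20) and
three curves; recovery benchmarks use 20 seeds × (200-point hinges,
500-sample step cohorts); the dilution property pools 20 seeds × 2,000
samples. Everything completes in well under a minute on one CPU.

## Known limitations

* The two-segment search is exhaustive OLS, as specified — no
  likelihood-based segmented regression, information-criterion model
  selection, or confidence interval on the split.
* The minimal scan $p$-value is selection-biased by design; treat the
  cutpoint as descriptive.
* Bady-model confidence intervals are not computed.
* VAF-based cellularity inherits every caveat of the 2·VAF
  approximation; flags are screening aids, not diagnoses, and the only
  action the package ever recommends is orthogonal re-testing.
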