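---
title: "Validating a liquid-biopsy NGS panel: QC gates, control charts and performance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a liquid-biopsy NGS panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidqc)
```

## The problem

Clinical laboratories that run targeted NGS panels on cell-free nucleic
acids (cfNA) from plasma must demonstrate, before reporting patient
results, that the assay's decision rules behave: that every quality gate
is applied with the intended boundary semantics, that batch controls keep
the process in statistical control, and that analytic sensitivity (limit
of detection), specificity and precision meet their acceptance criteria.
`liquidqc` implements that validation machinery for a panel reporting
three variant classes measured on two different scales:

* **fusions and exon-skipping transcripts** (e.g. SLC34A2-ROS1, EML4-ALK,
  MET exon 14 skipping), measured as UMI-deduplicated *molecular family*
  counts from circulating RNA;
* **copy-number amplifications** (CNAs; e.g. ERBB2/HER2, EGFR, MET, MYC,
  CDK6), measured as a *fold change* against a diploid baseline with an
  accompanying caller p-value.

The package does not touch reads: its domain begins at the summarized
variant-caller output (one row per target per sample) and the per-sample
run metrics, which is also the level at which laboratories review and
sign out results.

## The QC rule system

Three tiers of rules are applied, all parameterized by one
`qc_thresholds()` object so that no threshold ever lives at a call site.

**Sample level.** A specimen is analyzable when all of: total mapped
reads ≥ 10 million, coverage uniformity ≥ 95%, median molecular coverage
≥ 1500, molecular-based uniformity ≥ 80%, mean read length ≥ 80 bp, AQ20
bases ≥ 80%, and — for copy-number analysis — MAPD (median absolute
pairwise difference, a per-sample copy-number noise metric) strictly
below 0.4. The six sequencing gates are inclusive at the boundary; MAPD
is strict. A missing metric is a validation error, never a silent pass.

**Variant level.** A fusion/skipping call requires the sample's internal
process controls to certify RNA integrity — at least one expression
control (TBP or HMBS) *and* at least one MET wild-type exon junction
(E6-E7 or E11-E12) at ≥ 3 molecular copies — and the variant itself at
≥ 3 molecular copies. A CNA call requires fold change ≥ 1.15 *and*
p-value < 1e-5, and is `invalid` when the sample's MAPD gate fails.
Every observation receives exactly one of `detected`, `not_detected`,
`invalid`.

On the CNA ratio boundary: the assay's documentation states the gate
both as "> 1.15" and, in one sentence, as a "≥ 1.5-fold gain", while its
reported call tables are headed "≥ 1.15-fold gain". We treat 1.15 as
operative and the comparison as inclusive (`>= 1.15`), matching the
reported calls; the 1.5 figure is taken to be typographical. The choice
only matters for measurements exactly at the boundary.

**Batch level.** Each batch carries an analytic positive control (a
contrived mixture representing every monitored variant class) and a
no-template control. The batch passes only when the positive control
shows *every* expected variant as detected and the NTC looks empty:
≤ 6 million mapped reads *or* ≤ 45 bp mean read length, *and* zero
detected variants. The sentence defining NTC acceptance is grammatically
ambiguous; we fix the conjunction with variant-freedom (an NTC with a
detected variant can never pass — it is the contamination alarm) and keep
the literal "or" between the two sequencing metrics.

## Control charts

Batch positive controls are trended on Levey-Jennings charts. Fusion
control transcripts are first normalized to the arithmetic mean of the
four internal process-control counts
(`normalize_to_internal_controls()`, with a configurable rescaling
constant, since it is not stated whether plotted values are rescaled
reads or pure ratios); CNA controls are charted as fold change. QC
limits are the baseline mean ± 3 sample standard deviations
(`derive_limits()`), and `evaluate_point()` classifies with
closed-interval containment — a value exactly at a limit is in control,
a choice we document because the convention is not stated. No Westgard
multi-rules are applied; only the ±3 SD rule is in scope. Sample SD
(n − 1) is used throughout, the convention verified by reproducing every
printed replicate CV (see below). Negative lower limits are not floored
at zero by default; flooring is an option.

## Validation statistics

`replicate_summary()` computes mean, sample SD and CV per cent, plus
display strings rounded half-away-from-zero (600.5 prints as 601, as on
laboratory reports, where IEEE half-to-even would give 600). The n − 1
convention is not merely customary here: on the two-replicate dilution
rows, population SD would print a CV of 8.6% where the validated report
shows 12.1%, so reproducing the reported tables pins the convention.

`determine_lod()` defines the limit of detection as the lowest
concentration whose QC-valid replicates are all detected, scanning from
the most concentrated point and stopping at the first dip below 100% —
the "consistently detected down to dilution k" reading. A probit-style
LOD95 fit is deliberately out of scope: the validated design is a small
five-point series with 2–3 replicates per point, far below what a dose-
response fit needs. On the bundled series this yields 42 molecular
copies (fusion, dilution 5) and a 1.40-fold change (CNA, dilution 3).

`specificity()` computes per-donor and pooled specificity
(`100 · (assayed − detected) / assayed`) for each variant class, with
pooled counts constrained to equal per-donor sums. QC-failed donors are
excluded with a warning rather than silently absorbed.

`precision_analysis()` takes the long-format study table (specimen ×
target × run/day × operator × instrument × replicate) and reports, per
variant class: the hit rate; the repeatability CV per event (CV of the
triplicate measurements within the repeatability run); and the
intermediate-precision CV per event (CV of per-run mean measurements
across runs). Intermediate precision is a simple pooled CV across runs,
not an ANOVA variance-component decomposition — the validated report
quotes single CVs with no components, so a nested random-effects
decomposition (which the study design would in principle support) is
noted as an extension, and the per-day / per-operator / per-instrument
breakdowns are available as optional groupings. Censoring follows
laboratory practice: an event-run that fails QC on the initial run *and*
its rerun is censored — removed from both the expected count and the CV
— while a single sub-threshold measurement counts as a miss in the hit
rate and is excluded only from that run's CV cell. With three
single-fusion specimens and five CNA events over a triplicate
repeatability run plus three further single-replicate runs, this gives
18 fusion detection opportunities and 30 CNA opportunities (29 after one
censored event-run).

## The synthetic assay generator

No instrument data ships with the package; `assay_profile()` +
`make_*()` generate tables with the statistical structure the validation
assumes, so every stage is testable end to end.

* **Fusion counts** are negative binomial with
  `variance = mu + dispersion · mu²`; dispersion 0 degenerates to
  Poisson. Overdispersion is needed because observed replicate CVs
  (8.6–23%) exceed pure-Poisson CV at means of 42–601 molecular copies;
  the default dispersion 0.02 puts simulated CVs in that observed band.
  The distributional family itself is a modeling choice — the validated
  data carry no distributional statement — which is why it is a profile
  parameter rather than a constant.
* **Dilution calibration.** The default neat mean is 601 with dilution
  factors `(601, 293, 157, 82, 42)/601`, i.e. the generator's expected
  series means are exactly the validated series means. Likewise the CNA
  arm: true gain 5.36 at tumor fraction 1, with per-dilution tumor
  fractions `(1, 1.30/4.36, 0.40/4.36, 0.02, 0.01)` giving expected fold
  changes 5.36, 2.30, 1.40 at dilutions 1–3 and sub-gate means (≈1.09,
  ≈1.04) at dilutions 4–5, reproducing the validated detection pattern
  (fusions detected everywhere; CNAs only down to dilution 3).
* **CNA noise and p-values.** Fold change is
  `1 + (gain − 1) · tumor_fraction + N(0, sd)` floored at a configured
  minimum, with `sd = 0.02` — the replicate SD observed at the dilution
  where tumor signal is weakest and additive noise dominates. The vendor
  caller's p-value definition is opaque, so the simulator owns a
  documented stand-in (`cna_p_value()`): the one-sided normal tail of
  the standardized excess over 1.0, with p = 1 exactly at no excess.
  The engine treats p-values as opaque numbers to threshold, so any
  monotone surrogate with the right tail behaviour serves.
* **Negative cohorts** draw fusion background at a mean of 0.01 spurious
  molecular families per target — fusion-supporting UMI families are
  essentially absent in healthy-donor cfRNA, with rare singleton
  artifacts — and CNA fold changes fluctuating around 1.0 at the profile
  noise. Under these defaults the probability that any of the 1284
  targets of a 12-donor cohort clears its call gate is of order 1e-4,
  and a test sweeps 100 cohorts expecting zero detections.
* **Precision studies** use multiplicative lognormal run and replicate
  effects. Defaults: within-run CV 20% and between-run CV 8% for fusion
  counts, 2% and 5% for CNA fold changes, with CNA event levels 3.0 and
  2.5 (high) and 1.45/1.40/1.35 (low, i.e. placed near the 1.40-fold
  LOD as a precision study of low-positive specimens should be).

All generator randomness flows through explicit seeds (`profile$seed` or
a per-call `seed` argument); there is no hidden global state, and
identical seeds give bitwise-identical tables.

**What the generator does not emulate.** Read-level artifacts (strand
bias, UMI collisions, barcode hopping), batch-correlated drift,
extraction-efficiency variation between donors, and any dependence
between targets within a sample — targets are conditionally independent
given the profile. Passing tests therefore demonstrate that the decision
machinery and statistics are correct under the assay's assumed
measurement model, not that the physical assay meets its claims.

## Numerical and degenerate-input choices

* Rounding of display values is half-away-from-zero with a 1e-9 relative
  guard against binary misrepresentation of decimal ties.
* `replicate_summary()` refuses a zero mean with nonzero values (CV
  undefined) and returns `NA` SD for singletons.
* A dilution with no QC-valid replicate is flagged and excluded from
  detection rates; an LOD is undefined (with a warning) when even the
  most concentrated dilution misses.
* `derive_limits()` requires ≥ 2 baseline values; degenerate constant
  baselines give zero-width limits that still classify their own value
  as in control.
* Table round trips: integers are bit-exact; reals survive to better
  than 1e-12 (17 significant digits on disk).

## Problem sizes

The shipped analyses and tests use the validated study sizes throughout:
14-replicate five-point dilution series, a 12-donor negative cohort with
95 fusion + 12 CNA targets per donor, a 5-specimen precision study over
4 runs, and a 7-run control baseline. Monte-Carlo checks use 1000
replicate draws for mean recovery and 200 simulated studies (600
triplicate cells) for CV recovery, comparing against an independently
coded brute-force oracle rather than against the nominal parameter,
because the sample CV of a triplicate is a biased estimator of the true
CV and the comparison must target the estimator's own expectation.

## Known limitations

* Intermediate precision is a pooled CV, not variance components; see
  above.
* The control-chart module implements only the ±3 SD rule used in the
  validated workflow.
* Specificity is computed against fixed per-sample target counts; panels
  with per-sample target dropout would need the assayed counts taken
  from the table rather than the design.
* The simulator's independence assumptions make it unsuitable for
  studying cross-target contamination or carry-over, which the NTC rule
  exists to catch in practice.
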