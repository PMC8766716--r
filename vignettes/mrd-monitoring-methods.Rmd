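---
title: "Error-aware ctDNA calling and MRD monitoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-aware ctDNA calling and MRD monitoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdcall)
library(dplyr)
```

## The problem

After resection of a colorectal tumor, residual disease sheds trace amounts
of tumor-derived DNA (ctDNA) into plasma. Tumor-informed monitoring tracks
one to three somatic point mutations, identified in the resected tumor, in
serial plasma samples by deep amplicon sequencing. Two hard limits govern
what such an assay can see:

1. **Template limitation.** One haploid genome weighs about 3 pg, so
   `m` ng of cell-free DNA (cfDNA) contains at most
   `floor(m * 1000 / 3)` amplifiable copies of any locus. With 25 ng
   input that is 8,333 copies, and a single mutant copy corresponds to
   a variant allele frequency (VAF) of 100/8333 ≈ 0.012%. No depth of
   sequencing recovers a molecule that never entered the reaction.
2. **Background error.** Polymerase and sequencing errors produce alt
   reads at mutation-free loci. Transitions (A↔G, C↔T) show roughly
   five-fold higher background than transversions (class medians near
   0.0016% and 0.0003% VAF), so a marker's mutation class largely sets
   its noise floor.

`mrdcall` implements both sides: the template-copy arithmetic
(`mass_to_copies()`, `theoretical_quantification_limit()`,
`required_mass_for_limit()`) and an empirical background-error model with
the calling rules built on it.

## The background-error model and limit of detection

For each marker, wild-type control samples (a panel of normals, typically
n = 9) are sequenced and each control's false-positive VAF is computed as
`100 * alt_reads / total_reads`. The limit of detection (LOD) follows the
empirical rule for a normal distribution:

$$\mathrm{LOD} = \bar{x} + k\,s, \qquad k = 3,$$

where $\bar{x}$ and $s$ are the mean and *sample* standard deviation
(n − 1 denominator) of the control false-positive percentages. With k = 3,
99.73% of background observations fall below the limit. A control cohort
with mean 0.0016% and SD 0.0007% gives an LOD of 0.0037%, i.e. one mutant
allele among `round(100 / 0.0037)` = 27,027 wild-type alleles.

Choices made here:

* **Sample SD (n − 1).** The convention is not forced by the estimator's
  use; the unbiased form is the standard choice at n = 9. The companion
  "±" figure quoted with a control mean is interpreted as an SD, not a
  standard error, because mean + 3 × SD reproduces the 0.0037% limit.
* **k = 3 is exposed, not hard-coded** (`lod_from_background(mean, sd, k)`),
  so a laboratory preferring a different false-positive budget can move it.
* **Markers without dedicated controls** should fall back to the median
  mean-error of their mutation class (`summarize_by_class()` provides the
  class medians); class is the dominant factor in background error.

## Calling rules

`call_marker()` applies, per marker:

* **Effective cutoff** `max(0.01%, marker LOD)`. The global 0.01% cutoff
  is the assay-wide quantification floor; taking the maximum with the
  marker's own LOD protects markers with elevated background (e.g. the
  noisiest transition contexts, whose mean error alone can reach 0.005%)
  from being called inside their noise.
* **Coverage gate** at 10,000 reads (one expected read at 0.01% VAF):
  below it a result is `insufficient_coverage`, not a decision. The assay
  aims at ≥100,000 reads; between 10,000 and 100,000 a call is still
  emitted since real clinical samples occasionally dip that low.
* **Replicate pooling** (`pool_replicates()`) sums alt and total reads
  across replicate PCRs before calling — integration of reads, not
  averaging of VAFs, so a deep replicate carries proportionally more
  weight and the pooled VAF is the mediant of the replicate VAFs.
* **Sample rule**: a sample is positive if *any* of its markers is
  positive; inconclusive only if every marker lacked coverage. The
  any-rule maximises sensitivity, which is the point of tracking several
  markers in parallel; it is a design choice, since no unique rule is
  dictated by the problem.

## The synthetic-data generator

The simulator emulates the statistical structure the analysis assumes,
nothing more:

* **Template sampling** is binomial: each of `C` copies is mutant with
  probability VAF/100. (Plasma-scale pools make the hypergeometric
  correction negligible.)
* **Amplification** is proportional, with an optional per-template
  Bernoulli `dropout` success probability as a minimal model of
  all-or-nothing amplification at low copy number. A full
  branching-process efficiency model is out of scope. Note that
  per-template thinning alone never makes split-input triplicates beat a
  single reaction with the same total mass — a per-reaction failure mode
  would be needed — so single-versus-pooled comparisons under dropout are
  exploratory (`compare_single_vs_pooled()` reports both designs).
* **Sequencing error** is symmetric per substitution class (defaults:
  transitions 1.6e-5/read, transversions 3e-6/read, indels 0), not
  per-position, because class-level medians are what characterises the
  assay. A read reports the variant with probability
  `f(1 − e) + (1 − f)e` for surviving mutant template fraction `f`.
* **Coverage** is drawn uniformly within ±20% of `coverage_target`
  (default 150,000); observed per-run depth spreads are wide and no
  particular distribution is privileged, so a bounded uniform is the
  least-committal choice.
* **Patient trajectories** (`simulate_patient_series()`): true VAF is 0
  until a clearance day (default 30 — tumor-derived alleles clear from
  circulation within a month of resection), then accrues linearly at a
  daily rate; clinically observed rates span roughly 0.003–0.012% per
  day. Growth is `rate × (day − clearance_day)`, capped at 100%.

What the generator does **not** model: FASTQ-level reads, alignment,
UMI/barcode consensus, homopolymer and indel error, strand asymmetry,
position-specific error motifs, batch effects. Tests passing on this
generator therefore demonstrate correctness of the statistical pipeline —
estimation, thresholding, pooling, power arithmetic — on data that satisfy
the model's assumptions, not robustness to artefacts real sequencing can
contain.

## Assay evaluation

* **Dilution linearity** is fitted in log10–log10 space
  (`linearity()`), because a 10-fold series spanning 45% down to
  0.0045% covers four orders of magnitude and a linear-space r² would be
  dominated entirely by the top level. Slope 1 and intercept 0 mean
  unbiased quantification; a multiplicative bias moves only the
  intercept. Levels with non-positive observed VAF cannot be
  log-transformed and are dropped with a warning; fewer than three usable
  levels is an error.
* **Sensitivity/specificity** (`sensitivity_specificity()`) reports raw
  confusion counts alongside percentages; with small cohorts the counts
  are the primary quantity and the percentages are always derived from
  them.
* **Detection power** (`detection_power()`) pairs the closed form
  `p_template = 1 − (1 − v)^(R·C)` — the probability that at least one
  mutant template enters any of `R` reactions of `C` copies — with a
  seeded simulation through the full pipeline (`p_detect`). The gap
  between the two is what error, finite depth and the cutoff cost beyond
  template limitation.

## Longitudinal monitoring

`first_positive_day()` runs the calling pipeline over a patient's serial
samples and returns the earliest positive day; `lead_time()` subtracts it
from the imaging-based relapse day; `accumulation_rate()` fits the
least-squares slope of VAF on day over positive samples (≥2 required,
otherwise `NA`); `cohort_summary()` aggregates a cohort.

Conventions:

* Days are integers relative to tumor resection (day 0); calendar parsing
  is out of scope.
* Medians of even-length sets are the midpoint of the two central order
  statistics.
* **Follow-up is summarised over patients contributing a lead time**
  (ctDNA detected). With the packaged 14-patient retrospective cohort the
  full-cohort convention would give a median follow-up of 343 days while
  the detected-only convention gives 381; the latter makes follow-up and
  lead time describe the same denominator and is the one used.
* Negative lead times (molecular detection *after* imaging) are
  representable but warned about, so the tool generalises beyond cohorts
  where they never occur.
* In the cohort table format, `n.d` (not detected) and `n.a` are parsed
  as missing values.

## Numerical choices and problem sizes

* Copy numbers are floored (a fractional template cannot amplify), with a
  1e-9 epsilon guarding `floor()` against 1/3-type floating error.
* Simulated studies in the test suite use cohort and replicate sizes
  chosen to make Monte-Carlo error small relative to the tolerance being
  asserted: background-error recovery pools 100 cohorts of 9 controls;
  dilution linearity uses 100 seeds at coverage 150,000 with a 300 ng
  template-rich input (the mass at which the 0.001% quantification limit
  holds, so template sampling does not dominate the lowest level);
  specificity uses 1,000 cohorts of 9 controls; rate recovery uses
  triplicate PCRs on a 30-day sampling grid, the regime in which a
  least-squares slope on ≥2 positive samples is stable to within 20%.
* Seeded runs restore the caller's RNG state on exit, so simulation
  functions with an explicit `seed` are pure.

## Known limitations

* The error model is per-class and symmetric; a locus with atypical
  context-specific error is only protected by its *own* control-derived
  LOD, which requires dedicated controls.
* Linear VAF growth is a local approximation of what is presumably
  exponential tumor regrowth; over the sampling windows used here the
  distinction is below measurement noise, but extrapolation beyond the
  observed window is not supported.
* The dropout knob models template loss, not reaction-level failure;
  conclusions about pooled-versus-single designs under failure-prone
  amplification need a per-reaction failure model this package does not
  include.
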