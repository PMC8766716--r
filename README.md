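# mrdcall

Error-aware detection of circulating tumor DNA (ctDNA) from deep amplicon
sequencing read counts, for tumor-informed minimal residual disease (MRD)
monitoring after cancer surgery.

A tumor-informed MRD assay tracks one to three somatic point mutations,
identified in a patient's resected tumor, in serial plasma samples. At the
relevant variant allele frequencies (VAF, mutant reads / total reads, here
in percent) two things limit detection: the number of cell-free DNA (cfDNA)
template molecules that enter the PCR (about 3 pg per haploid genome copy,
so 25 ng of cfDNA is only ~8,333 copies of each locus and a single mutant
copy is 0.012% VAF), and the background substitution error of sequencing,
which differs about five-fold between transition and transversion markers.

`mrdcall` provides, as plain functions over data frames:

* **Background-error model** — per-marker false-positive rates from
  wild-type control cohorts and the empirical-rule limit of detection
  (LOD = mean + *k*·SD, *k* = 3): `estimate_error_profile()`,
  `lod_from_background()`, `lod_to_allele_ratio()`, `summarize_by_class()`.
* **Calling** — replicate-PCR read pooling and positivity decisions at
  `max(0.01% cutoff, marker LOD)` with a coverage gate:
  `pool_replicates()`, `call_marker()`, `call_sample()`.
* **Template-copy arithmetic** — `mass_to_copies()`,
  `theoretical_quantification_limit()`, `required_mass_for_limit()`.
* **Simulator** — seeded, template-limited amplicon read counts: control
  cohorts, 10-fold dilution series, longitudinal patient trajectories
  (`sim_config()`, `simulate_*()`).
* **Assay evaluation** — log-log dilution linearity with `tidy()`/
  `glance()`/`autoplot()` support, sensitivity/specificity with raw
  counts, analytic vs simulated detection power (`linearity()`,
  `sensitivity_specificity()`, `detection_power()`,
  `compare_single_vs_pooled()`).
* **Longitudinal monitoring** — first ctDNA-positive day, lead time versus
  imaging-based relapse detection, ctDNA accumulation rates, cohort
  summaries (`first_positive_day()`, `lead_time()`, `accumulation_rate()`,
  `cohort_summary()`); a 14-patient retrospective cohort table ships in
  `inst/extdata/retrospective_cohort.tsv`.

## Worked example

Characterise a KRAS c.35G>A (p.Gly12Asp) marker on simulated wild-type
controls, then call a patient follow-up sample from triplicate PCR counts:

```r
library(mrdcall)

panel <- marker_panel(data.frame(marker_id = "KRAS_c35GA", gene = "KRAS",
                                 hgvs_c = "c.35G>A", hgvs_p = "p.Gly12Asp"))

cfg <- sim_config(coverage_target = 115000)
controls <- simulate_control_cohort(9, marker_id = "KRAS_c35GA",
                                    cfg = cfg, seed = 42)
estimate_error_profile(controls)
#> # A tibble: 1 × 6
#>   marker_id  n_controls mean_fp_pct sd_fp_pct     k lod_pct
#> 1 KRAS_c35GA          9     0.00217   0.00148     3 0.00662
```

Nine controls give a mean background of 0.00217% VAF with SD 0.00148%, so
this marker's limit of detection is 0.00217 + 3 × 0.00148 = 0.0066% —
one mutant allele in `lod_to_allele_ratio(0.00662)` = 15,100 — below the
assay-wide 0.01% cutoff, which therefore remains the effective threshold:

```r
counts <- tibble::tibble(sample_id = "followup_d120", marker_id = "KRAS_c35GA",
                         replicate = 1:3, alt_reads = c(21L, 17L, 25L),
                         total_reads = c(48211L, 50102L, 46007L))
call_marker(pool_replicates(counts), estimate_error_profile(controls))
#> # A tibble: 1 × 8
#>   sample_id     marker_id  ... vaf_pct cutoff_pct status
#> 1 followup_d120 KRAS_c35GA ...  0.0437       0.01 positive
```

The 63 alt reads in 144,320 pooled reads are 0.0437% VAF, above the
cutoff: the sample is ctDNA-positive. Cohort-level monitoring works the
same way from a patient table:

```r
pts <- read_patient_table(system.file("extdata", "retrospective_cohort.tsv",
                                      package = "mrdcall"))
s <- cohort_summary(pts)
#> 14 patients, 13 ctDNA-detected, median age 68,
#> median lead time over imaging 112 days (range 0-226)
```

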