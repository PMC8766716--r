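Package: mrdcall
Title: Error-Aware Low-Frequency ctDNA Calling and Longitudinal MRD Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tumor-informed circulating tumor DNA (ctDNA) detection
    from deep amplicon sequencing read counts. Implements background-error
    limits of detection from wild-type control cohorts (mean plus k standard
    deviations), replicate-PCR read pooling, variant calling against a 0.01
    percent VAF cutoff, template-copy arithmetic for theoretical detection
    limits, a seeded simulator of template-limited amplicon sequencing,
    assay-evaluation routines (dilution-series linearity, sensitivity and
    specificity, analytic and simulated detection power), and longitudinal
    patient monitoring with lead-time analysis relative to imaging-based
    detection of relapse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
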