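# Shared fixtures built in code.

retrospective_cohort_path <- function() {
  system.file("extdata", "retrospective_cohort.tsv", package = "mrdcall")
}

# A small three-marker panel spanning both substitution classes and an indel.
toy_panel <- function() {
  marker_panel(data.frame(
    marker_id = c("KRAS_c35GA", "KRAS_c35GT", "EGFR_del"),
    gene = c("KRAS", "KRAS", "EGFR"),
    hgvs_c = c("c.35G>A", "c.35G>T", "c.2235_2249del"),
    hgvs_p = c("p.Gly12Asp", "p.Gly12Val", NA)
  ))
}

# Deterministic count table: 2 samples x 1 marker x 3 replicates.
toy_counts <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    marker_id = "KRAS_c35GA",
    replicate = rep(1:3, 2),
    alt_reads = c(2L, 0L, 3L, 60L, 55L, 65L),
    total_reads = c(50000L, 60000L, 40000L, 50000L, 50000L, 50000L)
  )
}
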