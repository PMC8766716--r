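#' Simulation configuration for template-limited amplicon sequencing
#'
#' Bundles the knobs of the read-count simulator. Defaults reflect the
#' assay regime the package targets: deep amplicon sequencing at roughly
#' 150,000 reads per target, per-read substitution error of 1.6e-5 for
#' transition markers and 3e-6 for transversions (class medians of
#' 0.0016\% and 0.0003\% VAF), 20 ng of cfDNA per PCR, and no
#' amplification dropout.
#'
#' @param coverage_target Mean reads per target; actual coverage is drawn
#'   uniformly within +/-20\% of this, mimicking observed run-to-run depth
#'   spread.
#' @param error_rate_by_class Named numeric vector of per-read substitution
#'   probabilities by mutation class; indels default to 0.
#' @param input_mass_ng cfDNA mass per PCR reaction in ng.
#' @param replicates PCR replicates per sample.
#' @param dropout Per-template amplification success probability in (0, 1];
#'   1 means every template amplifies. Values below 1 model the
#'   all-or-nothing amplification seen at low template copy numbers.
#' @param pg_per_copy Picograms of DNA per haploid genome copy.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(coverage_target = 150000,
                       error_rate_by_class = c(transition = 1.6e-5,
                                               transversion = 3e-6,
                                               insertion = 0, deletion = 0,
                                               delins = 0),
                       input_mass_ng = 20,
                       replicates = 1,
                       dropout = 1,
                       pg_per_copy = 3) {
  stopifnot(coverage_target >= 1, replicates >= 1)
  if (any(error_rate_by_class < 0) || any(error_rate_by_class > 1) ||
      dropout < 0 || dropout > 1) {
    rlang::abort("Probabilities must lie in [0, 1].",
                 class = "mrdcall_domain_error")
  }
  structure(list(coverage_target = coverage_target,
                 error_rate_by_class = error_rate_by_class,
                 input_mass_ng = input_mass_ng,
                 replicates = as.integer(replicates),
                 dropout = dropout,
                 pg_per_copy = pg_per_copy),
            class = "sim_config")
}

class_error_rate <- function(cfg, mutation_class) {
  e <- cfg$error_rate_by_class[mutation_class]
  e[is.na(e)] <- 0
  unname(e)
}

with_optional_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Draw mutant and wild-type template copies from plasma
#'
#' Template molecules entering a PCR are a binomial sample of the plasma
#' pool: each of `copies` templates is mutant independently with
#' probability `true_vaf_pct / 100`. At low copy numbers this sampling, not
#' sequencing error, dominates detection failure.
#'
#' @param copies Integer vector, template copies per reaction (>= 0).
#' @param true_vaf_pct True variant allele frequency in percent, in
#'   \[0, 100\]. Recycled against `copies`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A tibble with columns `copies`, `true_vaf_pct`,
#'   `mutant_copies`, `wt_copies` (the two always summing to `copies`).
#' @export
sample_templates <- function(copies, true_vaf_pct, seed = NULL) {
  if (any(copies < 0)) {
    rlang::abort("`copies` must be non-negative.", class = "mrdcall_domain_error")
  }
  if (any(true_vaf_pct < 0) || any(true_vaf_pct > 100)) {
    rlang::abort("`true_vaf_pct` must lie in [0, 100].",
                 class = "mrdcall_domain_error")
  }
  n <- max(length(copies), length(true_vaf_pct))
  copies <- rep_len(as.integer(copies), n)
  vaf <- rep_len(true_vaf_pct, n)
  mutant <- with_optional_seed(seed, stats::rbinom(n, copies, vaf / 100))
  tibble::tibble(copies = copies, true_vaf_pct = vaf,
                 mutant_copies = mutant, wt_copies = copies - mutant)
}

#' Sequence a template pool into alt/total read counts
#'
#' Models one PCR-plus-sequencing reaction: optional Bernoulli dropout
#' thins mutant and wild-type templates independently, the surviving
#' templates are amplified proportionally, and reads are drawn at a depth
#' uniform within +/-20\% of `coverage_target`. Each read reports the
#' variant allele with probability `f * (1 - e) + (1 - f) * e`, where `f`
#' is the surviving mutant template fraction and `e` the per-read
#' substitution error for the marker's mutation class.
#'
#' @param mutant_copies,wt_copies Integer vectors of template copies
#'   entering each reaction (recycled to a common length).
#' @param mutation_class Mutation class string(s) used to look up the error
#'   rate; default `"transition"`.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `replicate`, `alt_reads`, `total_reads`,
#'   plus the surviving template tallies `mutant_templates`,
#'   `wt_templates`. Errors with class `mrdcall_library_failure` if a
#'   reaction ends with zero surviving templates.
#' @export
sequence_reads <- function(mutant_copies, wt_copies,
                           mutation_class = "transition",
                           cfg = sim_config(), seed = NULL) {
  n <- max(length(mutant_copies), length(wt_copies), length(mutation_class))
  mut <- rep_len(as.integer(mutant_copies), n)
  wt <- rep_len(as.integer(wt_copies), n)
  cls <- rep_len(mutation_class, n)
  if (any(mut < 0) || any(wt < 0)) {
    rlang::abort("Template counts must be non-negative.",
                 class = "mrdcall_domain_error")
  }
  if (any(mut + wt < 1)) {
    rlang::abort("A reaction with zero templates yields no library.",
                 class = "mrdcall_library_failure")
  }
  e <- class_error_rate(cfg, cls)
  with_optional_seed(seed, {
    mut_s <- if (cfg$dropout < 1) stats::rbinom(n, mut, cfg$dropout) else mut
    wt_s <- if (cfg$dropout < 1) stats::rbinom(n, wt, cfg$dropout) else wt
    if (any(mut_s + wt_s == 0)) {
      rlang::abort("All templates dropped out; no amplifiable library.",
                   class = "mrdcall_library_failure")
    }
    coverage <- as.integer(round(stats::runif(
      n, 0.8 * cfg$coverage_target, 1.2 * cfg$coverage_target)))
    f <- mut_s / (mut_s + wt_s)
    p <- f * (1 - e) + (1 - f) * e
    alt <- stats::rbinom(n, coverage, p)
    tibble::tibble(replicate = seq_len(n), alt_reads = alt,
                   total_reads = coverage,
                   mutant_templates = mut_s, wt_templates = wt_s)
  })
}

#' Simulate a wild-type control cohort for background-error estimation
#'
#' Generates read counts for `n_controls` mutation-free cfDNA samples at a
#' marker. Every alt read is a sequencing substitution error, so the
#' resulting table is the substrate for [estimate_error_profile()].
#'
#' @param n_controls Number of control individuals (>= 2; a standard
#'   deviation needs at least two observations). Default 9.
#' @param marker_id Marker identifier attached to the output.
#' @param mutation_class Mutation class used for the error rate.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample_id`, `marker_id`, `replicate`,
#'   `alt_reads`, `total_reads`.
#' @export
simulate_control_cohort <- function(n_controls = 9, marker_id = "marker",
                                    mutation_class = "transition",
                                    cfg = sim_config(), seed = NULL) {
  if (n_controls < 2) {
    rlang::abort("At least 2 controls are required to estimate an SD.",
                 class = "mrdcall_config_error")
  }
  copies <- mass_to_copies(cfg$input_mass_ng, cfg$pg_per_copy)
  with_optional_seed(seed, {
    reads <- sequence_reads(rep(0L, n_controls), rep(copies, n_controls),
                            mutation_class = mutation_class, cfg = cfg)
    tibble::tibble(sample_id = sprintf("control_%02d", seq_len(n_controls)),
                   marker_id = marker_id, replicate = 1L,
                   alt_reads = reads$alt_reads,
                   total_reads = reads$total_reads)
  })
}

#' Simulate a serial dilution of mutant into wild-type cfDNA
#'
#' Emulates a `fold`-wise dilution series starting at `start_vaf_pct`
#' (default: 10-fold steps from 45\% down to 0.0045\% over five levels).
#' Each level draws templates at its expected VAF and sequences them, so
#' observed VAFs carry both template-sampling and sequencing noise.
#'
#' @param start_vaf_pct Highest expected VAF in percent (default 45).
#' @param fold Dilution factor per step (default 10).
#' @param levels Number of levels (>= 1; default 5).
#' @param marker_id,mutation_class Marker identity for the counts.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `level`, `expected_vaf_pct`, `marker_id`,
#'   `replicate`, `alt_reads`, `total_reads`, `observed_vaf_pct`.
#' @export
simulate_dilution_series <- function(start_vaf_pct = 45, fold = 10,
                                     levels = 5, marker_id = "marker",
                                     mutation_class = "transition",
                                     cfg = sim_config(), seed = NULL) {
  stopifnot(start_vaf_pct <= 100, levels >= 1, fold > 1)
  expected <- start_vaf_pct / fold^(seq_len(levels) - 1)
  copies <- mass_to_copies(cfg$input_mass_ng, cfg$pg_per_copy)
  with_optional_seed(seed, {
    templ <- sample_templates(rep(copies, levels), expected)
    reads <- sequence_reads(templ$mutant_copies, templ$wt_copies,
                            mutation_class = mutation_class, cfg = cfg)
    tibble::tibble(level = seq_len(levels), expected_vaf_pct = expected,
                   marker_id = marker_id, replicate = 1L,
                   alt_reads = reads$alt_reads,
                   total_reads = reads$total_reads,
                   observed_vaf_pct = 100 * reads$alt_reads / reads$total_reads)
  })
}

#' Simulate a longitudinal post-resection patient series
#'
#' Models minimal residual disease kinetics after tumor resection: true
#' ctDNA VAF is zero until `clearance_until_day` (initial clearance of
#' tumor-derived alleles from circulation), then accrues linearly at
#' `daily_rate_pct` percent per day toward clinical relapse. Each sampling
#' day yields `cfg$replicates` PCR replicates of read counts per marker.
#'
#' @param marker_id Marker identifier (single marker per call).
#' @param mutation_class Mutation class for the error rate.
#' @param relapse_day Day of imaging-detectable relapse (used only to cap
#'   the series; growth continues through it).
#' @param daily_rate_pct ctDNA accumulation rate in percent VAF per day
#'   (observed clinical range roughly 0.003-0.012).
#' @param clearance_until_day Day until which true VAF is zero (default 30).
#' @param sampling_days Strictly increasing integer vector of sampling days
#'   since resection.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `day`, `true_vaf_pct`, `marker_id`,
#'   `replicate`, `alt_reads`, `total_reads`.
#' @export
simulate_patient_series <- function(marker_id = "marker",
                                    mutation_class = "transition",
                                    relapse_day, daily_rate_pct,
                                    clearance_until_day = 30,
                                    sampling_days, cfg = sim_config(),
                                    seed = NULL) {
  if (is.unsorted(sampling_days, strictly = TRUE)) {
    rlang::abort("`sampling_days` must be strictly increasing.",
                 class = "mrdcall_input_error")
  }
  if (daily_rate_pct < 0) {
    rlang::abort("`daily_rate_pct` must be non-negative.",
                 class = "mrdcall_domain_error")
  }
  true_vaf <- pmin(100, daily_rate_pct * pmax(0, sampling_days - clearance_until_day))
  copies <- mass_to_copies(cfg$input_mass_ng, cfg$pg_per_copy)
  grid <- tidyr::expand_grid(day_index = seq_along(sampling_days),
                             replicate = seq_len(cfg$replicates))
  with_optional_seed(seed, {
    templ <- sample_templates(rep(copies, nrow(grid)),
                              true_vaf[grid$day_index])
    reads <- sequence_reads(templ$mutant_copies, templ$wt_copies,
                            mutation_class = mutation_class, cfg = cfg)
    tibble::tibble(day = sampling_days[grid$day_index],
                   true_vaf_pct = true_vaf[grid$day_index],
                   marker_id = marker_id,
                   replicate = grid$replicate,
                   alt_reads = reads$alt_reads,
                   total_reads = reads$total_reads)
  })
}
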