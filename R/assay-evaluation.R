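#' Dilution-series linearity in log-log space
#'
#' Fits observed VAF against expected VAF on log10-log10 axes by least
#' squares. A dilution series spans several orders of magnitude, so the
#' log-log fit weights every level equally where a linear-space fit would
#' be dominated by the top level; a well-behaved assay gives slope near 1
#' and r-squared near 1. Levels with a non-positive observed VAF cannot be
#' log-transformed and are dropped with a warning.
#'
#' @param data A data frame with columns `expected_vaf_pct` and
#'   `observed_vaf_pct`.
#' @return An object of class `mrd_linearity`: a list with `slope`,
#'   `intercept`, `r_squared`, `n_levels`, the underlying `lm` `fit`, and
#'   the usable `data`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' linearity(data.frame(expected_vaf_pct = c(45, 4.5, 0.45),
#'                      observed_vaf_pct = c(44, 4.4, 0.46)))
#' @export
linearity <- function(data) {
  required <- c("expected_vaf_pct", "observed_vaf_pct")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    rlang::abort(paste0("Series lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mrdcall_format_error")
  }
  usable <- data$expected_vaf_pct > 0 & data$observed_vaf_pct > 0
  if (any(!usable)) {
    rlang::warn(sprintf(
      "%d level(s) with non-positive VAF excluded from the log-log fit.",
      sum(!usable)))
  }
  data <- data[usable, , drop = FALSE]
  if (nrow(data) < 3) {
    rlang::abort("Fewer than 3 usable dilution levels; cannot assess linearity.",
                 class = "mrdcall_evaluation_error")
  }
  fit <- stats::lm(log10(observed_vaf_pct) ~ log10(expected_vaf_pct),
                   data = data)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_levels = nrow(data),
                 fit = fit,
                 data = tibble::as_tibble(data)),
            class = "mrd_linearity")
}

#' @export
print.mrd_linearity <- function(x, ...) {
  cat("Dilution-series linearity (log10-log10 least squares)\n")
  cat(sprintf("  levels: %d   slope: %.4f   intercept: %.4f   r-squared: %.4f\n",
              x$n_levels, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dilution-linearity fit
#'
#' @param x An `mrd_linearity` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.mrd_linearity <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "log10(expected_vaf_pct)"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a dilution-linearity fit
#'
#' @param x An `mrd_linearity` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `slope`, `intercept`,
#'   `n_levels`.
#' @export
glance.mrd_linearity <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, n_levels = x$n_levels)
}

#' Sensitivity and specificity of calls against known truth
#'
#' Compares positivity calls with known sample truth (mutant vs wild
#' type). Counts are reported alongside percentages because small cohorts
#' make the raw fractions (e.g. 23/25) the primary quantity; percentages
#' are computed from the counts, never stated independently of them.
#' Inconclusive calls (`insufficient_coverage`) are excluded and counted.
#'
#' @param calls A tibble with a `status` column (`"positive"`,
#'   `"wild_type"`, `"insufficient_coverage"`).
#' @param truth_is_mutant Logical vector, one element per call row: is the
#'   sample truly mutant?
#' @return A one-row tibble: `tp`, `fn`, `tn`, `fp`, `n_inconclusive`,
#'   `sensitivity_pct`, `specificity_pct`.
#' @export
sensitivity_specificity <- function(calls, truth_is_mutant) {
  if (nrow(calls) == 0) {
    rlang::abort("No calls to evaluate.", class = "mrdcall_evaluation_error")
  }
  if (length(truth_is_mutant) != nrow(calls)) {
    rlang::abort("One truth label per call row is required.",
                 class = "mrdcall_evaluation_error")
  }
  conclusive <- calls$status != "insufficient_coverage"
  pos <- calls$status[conclusive] == "positive"
  mut <- truth_is_mutant[conclusive]
  tp <- sum(pos & mut); fn <- sum(!pos & mut)
  tn <- sum(!pos & !mut); fp <- sum(pos & !mut)
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    n_inconclusive = sum(!conclusive),
    sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity_pct = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  )
}

#' Analytic probability that any mutant template enters the reaction(s)
#'
#' With `C` template copies per reaction, `R` replicates and true VAF `v`
#' (as a fraction), the chance that at least one mutant template is
#' sampled is `1 - (1 - v)^(R * C)` - the hard ceiling on detection
#' however deep the sequencing.
#'
#' @param input_mass_ng cfDNA mass per reaction in ng (> 0).
#' @param true_vaf_pct True VAF in percent.
#' @param replicates Number of PCR replicates.
#' @param pg_per_copy Picograms per haploid genome copy (default 3).
#' @return Numeric probability in \[0, 1\].
#' @export
p_template_present <- function(input_mass_ng, true_vaf_pct, replicates = 1,
                               pg_per_copy = 3) {
  if (any(input_mass_ng <= 0)) {
    rlang::abort("`input_mass_ng` must be positive.",
                 class = "mrdcall_domain_error")
  }
  copies <- mass_to_copies(input_mass_ng, pg_per_copy)
  1 - (1 - true_vaf_pct / 100)^(replicates * copies)
}

#' Detection power at a given input mass, VAF and replicate design
#'
#' Pairs the analytic template-presence probability with a seeded
#' simulation of the full pipeline: template sampling, optional dropout,
#' sequencing, replicate pooling and calling at the effective cutoff. The
#' gap between `p_template` and `p_detect` measures what sequencing error,
#' finite coverage and the cutoff cost on top of template limitation.
#'
#' @param input_mass_ng cfDNA mass per PCR reaction in ng.
#' @param true_vaf_pct True VAF in percent.
#' @param replicates PCR replicates pooled per sample.
#' @param cfg A [sim_config()] (its `input_mass_ng`/`replicates` are
#'   overridden by the arguments here).
#' @param n_sims Simulated samples (default 500).
#' @param cutoff_pct VAF cutoff used for calling (default 0.01).
#' @param mutation_class Marker class for the simulated error rate.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `input_mass_ng`, `replicates`,
#'   `true_vaf_pct`, `p_template`, `p_detect`, `n_sims`.
#' @export
detection_power <- function(input_mass_ng, true_vaf_pct, replicates = 1,
                            cfg = sim_config(), n_sims = 500,
                            cutoff_pct = 0.01,
                            mutation_class = "transition", seed = NULL) {
  stopifnot(input_mass_ng > 0, true_vaf_pct >= 0, replicates >= 1)
  copies <- mass_to_copies(input_mass_ng, cfg$pg_per_copy)
  p_template <- p_template_present(input_mass_ng, true_vaf_pct, replicates,
                                   cfg$pg_per_copy)
  detected <- with_optional_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      templ <- sample_templates(rep(copies, replicates), true_vaf_pct)
      reads <- tryCatch(
        sequence_reads(templ$mutant_copies, templ$wt_copies,
                       mutation_class = mutation_class, cfg = cfg),
        mrdcall_library_failure = function(e) NULL)
      if (is.null(reads)) return(FALSE)
      pooled <- pool_replicates(dplyr::mutate(reads, marker_id = "m"))
      call <- call_marker(pooled, global_cutoff_pct = cutoff_pct,
                          min_coverage = 1)
      call$status == "positive"
    }, logical(1))
  })
  tibble::tibble(input_mass_ng = input_mass_ng, replicates = replicates,
                 true_vaf_pct = true_vaf_pct, p_template = p_template,
                 p_detect = mean(detected), n_sims = n_sims)
}

#' Compare a single high-input PCR with pooled low-input triplicates
#'
#' Contrasts the two assay designs for low-level ctDNA: one PCR with
#' `mass_single` ng of template versus `replicates` pooled PCRs with
#' `mass_per_replicate` ng each. Under pure template sampling the single
#' 20-ng reaction sees more total template than 3 x 5 ng and wins; with
#' per-reaction dropout below 1, splitting the input across independent
#' reactions hedges against amplification failure and the pooled design
#' can come out ahead.
#'
#' @param mass_single ng in the single-PCR design (default 20).
#' @param mass_per_replicate ng per replicate in the pooled design
#'   (default 5).
#' @param replicates Replicates in the pooled design (default 3).
#' @param true_vaf_pct True VAF in percent (default 0.01).
#' @param cfg A [sim_config()]; its `dropout` applies to both designs.
#' @param n_sims,cutoff_pct,mutation_class,seed As in [detection_power()].
#' @return A two-row tibble (one per design) with a `design` column
#'   prepended to the [detection_power()] output.
#' @export
compare_single_vs_pooled <- function(mass_single = 20, mass_per_replicate = 5,
                                     replicates = 3, true_vaf_pct = 0.01,
                                     cfg = sim_config(), n_sims = 500,
                                     cutoff_pct = 0.01,
                                     mutation_class = "transition",
                                     seed = NULL) {
  with_optional_seed(seed, {
    single <- detection_power(mass_single, true_vaf_pct, replicates = 1,
                              cfg = cfg, n_sims = n_sims,
                              cutoff_pct = cutoff_pct,
                              mutation_class = mutation_class)
    pooled <- detection_power(mass_per_replicate, true_vaf_pct,
                              replicates = replicates, cfg = cfg,
                              n_sims = n_sims, cutoff_pct = cutoff_pct,
                              mutation_class = mutation_class)
    dplyr::bind_rows(
      dplyr::mutate(single, design = "single", .before = 1),
      dplyr::mutate(pooled, design = "pooled", .before = 1)
    )
  })
}
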