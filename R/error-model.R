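#' Limit of detection from background-error moments
#'
#' The empirical-rule limit of detection: mean background false-positive
#' VAF plus `k` standard deviations. With `k = 3`, 99.73\% of
#' normally-distributed background observations fall below the limit, so a
#' VAF at or above it is unlikely to be sequencing error. Applied to a
#' control-cohort mean of 0.0016\% and SD of 0.0007\% this gives 0.0037\%.
#'
#' @param mean_fp_pct Mean background false-positive VAF in percent.
#' @param sd_fp_pct Sample standard deviation of the background VAF in
#'   percent.
#' @param k SD multiplier (default 3, the empirical-rule choice).
#' @return Numeric, the limit of detection in percent VAF.
#' @examples
#' lod_from_background(0.0016, 0.0007)  # 0.0037
#' @export
lod_from_background <- function(mean_fp_pct, sd_fp_pct, k = 3) {
  if (any(mean_fp_pct < 0) || any(sd_fp_pct < 0) || any(k < 0)) {
    rlang::abort("Background moments and k must be non-negative.",
                 class = "mrdcall_domain_error")
  }
  mean_fp_pct + k * sd_fp_pct
}

#' Estimate per-marker background-error profiles from wild-type controls
#'
#' For each marker in a control count table, computes each control's
#' false-positive VAF (`100 * alt_reads / total_reads`), the cohort mean
#' and sample standard deviation (n - 1 denominator), and the derived
#' limit of detection `mean + k * SD`.
#'
#' @param controls A tibble of wild-type control counts with columns
#'   `marker_id`, `alt_reads`, `total_reads` (one row per control
#'   measurement; a `sample_id` column is carried through grouping but not
#'   required).
#' @param k SD multiplier for the LOD (default 3).
#' @return A tibble with one row per marker: `marker_id`, `n_controls`,
#'   `mean_fp_pct`, `sd_fp_pct`, `k`, `lod_pct`.
#' @export
estimate_error_profile <- function(controls, k = 3) {
  required <- c("marker_id", "alt_reads", "total_reads")
  missing <- setdiff(required, names(controls))
  if (length(missing)) {
    rlang::abort(paste0("Control table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mrdcall_format_error")
  }
  if (any(controls$total_reads <= 0)) {
    rlang::abort("Every control record needs total_reads > 0.",
                 class = "mrdcall_estimation_error")
  }
  out <- controls |>
    dplyr::mutate(fp_pct = 100 * .data$alt_reads / .data$total_reads) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(n_controls = dplyr::n(),
                     mean_fp_pct = mean(.data$fp_pct),
                     sd_fp_pct = stats::sd(.data$fp_pct),
                     .groups = "drop")
  if (any(out$n_controls < 2)) {
    rlang::abort("Each marker needs at least 2 control records.",
                 class = "mrdcall_estimation_error")
  }
  out |>
    dplyr::mutate(k = k,
                  lod_pct = lod_from_background(.data$mean_fp_pct,
                                                .data$sd_fp_pct, k))
}

#' Express a limit of detection as a 1-in-N allele ratio
#'
#' Converts a percent-VAF limit into "one mutant allele among N wild-type
#' alleles": `round(100 / lod_pct)`. A 0.0037\% limit corresponds to one
#' mutant allele out of 27,027.
#'
#' @param lod_pct Limit of detection in percent VAF (> 0).
#' @return Integer vector N.
#' @examples
#' lod_to_allele_ratio(0.0037)  # 27027
#' @export
lod_to_allele_ratio <- function(lod_pct) {
  if (any(lod_pct <= 0)) {
    rlang::abort("A zero or negative LOD has no allele-ratio form.",
                 class = "mrdcall_domain_error")
  }
  as.integer(round(100 / lod_pct))
}

#' Summarise background error by mutation class
#'
#' Joins per-marker error profiles to a marker panel and reports, per
#' mutation class present, the median, minimum and maximum of the mean
#' background false-positive rate. Mutation class (transition vs
#' transversion vs indel) is the dominant determinant of background error,
#' so this summary is what a fallback error rate for an uncharacterised
#' marker should be drawn from.
#'
#' @param profiles Output of [estimate_error_profile()].
#' @param markers A marker panel tibble with `marker_id` and
#'   `mutation_class` (see [marker_panel()]).
#' @return A tibble with one row per class: `mutation_class`, `n_markers`,
#'   `median_mean_fp_pct`, `min_mean_fp_pct`, `max_mean_fp_pct`.
#' @export
summarize_by_class <- function(profiles, markers) {
  unknown <- setdiff(profiles$marker_id, markers$marker_id)
  if (length(unknown)) {
    rlang::abort(paste0("Marker(s) not in panel: ",
                        paste(unknown, collapse = ", ")),
                 class = "mrdcall_lookup_error")
  }
  profiles |>
    dplyr::inner_join(markers[, c("marker_id", "mutation_class")],
                      by = "marker_id") |>
    dplyr::group_by(.data$mutation_class) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     median_mean_fp_pct = stats::median(.data$mean_fp_pct),
                     min_mean_fp_pct = min(.data$mean_fp_pct),
                     max_mean_fp_pct = max(.data$mean_fp_pct),
                     .groups = "drop")
}
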