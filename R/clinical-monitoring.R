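#' Read a longitudinal patient cohort table
#'
#' Ingests a tab-delimited cohort table with one row per patient and
#' columns `patient_id`, `sex`, `age`, `uicc`, `pt`, `pn`, `m`, `gene`,
#' `hgvs_c`, `hgvs_p`, `imaging_day`, `ctdna_day`, `delta`. The markers
#' `"n.d"` (not detected) and `"n.a"` (not applicable) in the day columns
#' are parsed as missing. Days are integers relative to tumor resection
#' (day 0). A transcription of the package's retrospective validation
#' cohort ships as `system.file("extdata", "retrospective_cohort.tsv",
#' package = "mrdcall")`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with typed columns; `ctdna_day`/`delta` are `NA` where
#'   ctDNA was never detected.
#' @export
read_patient_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = c("", "NA", "n.d", "n.a", "n.d.", "n.a."),
                       progress = FALSE)
  if (nrow(x) == 0) {
    rlang::abort("Patient table is empty.", class = "mrdcall_input_error")
  }
  required <- c("patient_id", "sex", "age", "gene", "hgvs_c",
                "imaging_day", "ctdna_day", "delta")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    rlang::abort(paste0("Patient table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mrdcall_format_error")
  }
  to_int <- function(col, name) {
    out <- suppressWarnings(as.integer(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad)) {
      rlang::abort(sprintf("Row %d: cannot parse %s value '%s'.",
                           bad[1], name, col[bad[1]]),
                   class = "mrdcall_format_error")
    }
    out
  }
  x |>
    dplyr::mutate(age = to_int(.data$age, "age"),
                  imaging_day = to_int(.data$imaging_day, "imaging_day"),
                  ctdna_day = to_int(.data$ctdna_day, "ctdna_day"),
                  delta = to_int(.data$delta, "delta"))
}

#' Earliest ctDNA-positive day per patient
#'
#' Runs the calling pipeline over a longitudinal count table (pooling
#' replicates within each patient-day, calling each marker, combining to a
#' sample call) and reports each patient's earliest positive day, or `NA`
#' if no sample was ever positive.
#'
#' @param series A tibble with columns `day`, `marker_id`, `alt_reads`,
#'   `total_reads`, optionally `patient_id` and `replicate`.
#' @param profiles,global_cutoff_pct,min_coverage Passed to
#'   [call_marker()].
#' @return A tibble with one row per patient: `patient_id`,
#'   `first_positive_day` (`NA` when never positive).
#' @export
first_positive_day <- function(series, profiles = NULL,
                               global_cutoff_pct = 0.01,
                               min_coverage = 10000) {
  if (nrow(series) == 0) {
    rlang::abort("Empty patient series.", class = "mrdcall_input_error")
  }
  if (!"patient_id" %in% names(series)) series$patient_id <- "patient"
  series |>
    dplyr::mutate(sample_id = paste(.data$patient_id, .data$day, sep = "@")) |>
    pool_replicates() |>
    call_marker(profiles = profiles, global_cutoff_pct = global_cutoff_pct,
                min_coverage = min_coverage) |>
    call_sample() |>
    tidyr::separate_wider_delim("sample_id", "@",
                                names = c("patient_id", "day")) |>
    dplyr::mutate(day = as.integer(.data$day)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_positive_day = if (any(.data$sample_status == "positive")) {
        min(.data$day[.data$sample_status == "positive"])
      } else NA_integer_,
      .groups = "drop")
}

#' Lead time of molecular over imaging-based relapse detection
#'
#' `delta_days = imaging_day - ctdna_day`: the number of days by which
#' ctDNA positivity preceded imaging-detectable recurrence. `NA` where
#' ctDNA was never detected. Negative leads (molecular detection after
#' imaging) are representable but flagged with a warning since they
#' usually indicate a data problem.
#'
#' @param imaging_day Integer vector of imaging-based relapse days.
#' @param ctdna_day Integer vector of first ctDNA-positive days (`NA` for
#'   not detected). Recycled against `imaging_day`.
#' @return A tibble: `imaging_day`, `ctdna_day`, `delta_days`.
#' @examples
#' lead_time(764, 647)  # 117 days
#' @export
lead_time <- function(imaging_day, ctdna_day) {
  n <- max(length(imaging_day), length(ctdna_day))
  imaging_day <- rep_len(as.integer(imaging_day), n)
  ctdna_day <- rep_len(as.integer(ctdna_day), n)
  if (any(is.na(imaging_day))) {
    rlang::abort("`imaging_day` must be present for lead-time analysis.",
                 class = "mrdcall_input_error")
  }
  delta <- imaging_day - ctdna_day
  if (any(delta < 0, na.rm = TRUE)) {
    rlang::warn("Negative lead time: ctDNA detected after imaging relapse.")
  }
  tibble::tibble(imaging_day = imaging_day, ctdna_day = ctdna_day,
                 delta_days = delta)
}

#' ctDNA accumulation rate from positive longitudinal samples
#'
#' Least-squares slope of VAF (percent) on day across a patient's
#' positive samples, i.e. the daily ctDNA accrual rate preceding clinical
#' relapse. At least two positive samples are required; otherwise the
#' rate is reported as `NA`.
#'
#' @param days Integer vector of sampling days.
#' @param vaf_pct Numeric vector of measured VAFs in percent, same length.
#' @param positive Logical vector marking which samples are
#'   ctDNA-positive; defaults to `vaf_pct > 0`.
#' @return Numeric scalar, percent VAF per day, or `NA_real_`.
#' @examples
#' accumulation_rate(c(0, 100), c(0.01, 1.21))  # 0.012
#' @export
accumulation_rate <- function(days, vaf_pct, positive = vaf_pct > 0) {
  stopifnot(length(days) == length(vaf_pct), length(positive) == length(days))
  days <- days[positive]
  vaf <- vaf_pct[positive]
  if (length(days) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(vaf ~ days))[2])
}

#' Cohort summary for a longitudinal monitoring study
#'
#' Medians and ranges across a patient cohort: age at resection,
#' follow-up until imaging-based relapse, and lead time (delta), plus the
#' detected fraction and per-gene marker counts. Medians of even-length
#' sets are the midpoint of the two central order statistics. Follow-up
#' is summarised over the patients contributing a lead time (those with
#' ctDNA detected), the denominator under which a cohort's follow-up and
#' delta describe the same patients.
#'
#' @param patients A cohort tibble as returned by [read_patient_table()].
#' @return A list: `n_patients`, `n_detected`, `detected_fraction`,
#'   `sex_counts`, `age` (median/min/max), `followup_days`
#'   (median/min/max over detected patients), `delta_days`
#'   (median/min/max), and `gene_counts` (tibble).
#' @export
cohort_summary <- function(patients) {
  if (nrow(patients) < 1) {
    rlang::abort("Empty cohort.", class = "mrdcall_input_error")
  }
  detected <- !is.na(patients$ctdna_day)
  rng <- function(x) {
    x <- x[!is.na(x)]
    list(median = stats::median(x), min = min(x), max = max(x))
  }
  gene_counts <- patients |>
    dplyr::count(.data$gene, name = "n_markers") |>
    dplyr::arrange(dplyr::desc(.data$n_markers))
  list(
    n_patients = nrow(patients),
    n_detected = sum(detected),
    detected_fraction = sum(detected) / nrow(patients),
    sex_counts = table(patients$sex),
    age = rng(patients$age),
    followup_days = rng(patients$imaging_day[detected]),
    delta_days = rng(patients$delta),
    gene_counts = gene_counts
  )
}

#' Write a cohort summary as JSON
#'
#' @param summary Output of [cohort_summary()].
#' @param path Output file path.
#' @return The summary, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  out <- summary
  out$sex_counts <- as.list(out$sex_counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
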