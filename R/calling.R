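#' Variant allele frequency from read counts
#'
#' `100 * alt_reads / total_reads`, in percent.
#'
#' @param alt_reads,total_reads Integer vectors; `total_reads` must be
#'   positive and `alt_reads` between 0 and `total_reads`.
#' @return Numeric vector of VAFs in percent.
#' @examples
#' compute_vaf(35, 100000)  # 0.035
#' @export
compute_vaf <- function(alt_reads, total_reads) {
  if (any(total_reads <= 0)) {
    rlang::abort("VAF is undefined at zero coverage.",
                 class = "mrdcall_domain_error")
  }
  if (any(alt_reads < 0) || any(alt_reads > total_reads)) {
    rlang::abort("Need 0 <= alt_reads <= total_reads.",
                 class = "mrdcall_domain_error")
  }
  100 * alt_reads / total_reads
}

#' Pool replicate PCRs by read summation
#'
#' Integrates sequencing reads across replicate PCRs of the same marker by
#' summing alt and total read tallies, the pooling that lets three 5-ng
#' reactions be read as one 15-ng measurement. Pooling is per marker
#' within each sample when a `sample_id` column is present.
#'
#' @param counts A tibble with columns `marker_id`, `alt_reads`,
#'   `total_reads`, optionally `sample_id` and `replicate`.
#' @return One row per (sample, marker): the summed `alt_reads` and
#'   `total_reads`, `n_replicates`, and `replicate = "pooled"`.
#' @examples
#' pool_replicates(tibble::tibble(marker_id = "m",
#'                                alt_reads = c(2, 0, 3),
#'                                total_reads = c(50000, 60000, 40000)))
#' @export
pool_replicates <- function(counts) {
  if (nrow(counts) < 1) {
    rlang::abort("Need at least one replicate to pool.",
                 class = "mrdcall_input_error")
  }
  keys <- intersect(c("sample_id", "marker_id"), names(counts))
  if (!"marker_id" %in% keys) {
    rlang::abort("Count table lacks a marker_id column.",
                 class = "mrdcall_format_error")
  }
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     alt_reads = sum(.data$alt_reads),
                     total_reads = sum(.data$total_reads),
                     .groups = "drop") |>
    dplyr::mutate(replicate = "pooled")
}

#' Call markers against the VAF cutoff and marker-specific LOD
#'
#' Applies the positivity decision to (pooled) per-marker read counts. The
#' effective threshold for a marker is the larger of the global cutoff
#' (default 0.01\% VAF) and the marker's background-error limit of
#' detection, so markers with elevated background (e.g. noisy transition
#' contexts) are never called below their own noise floor. Markers covered
#' below `min_coverage` reads are reported as `insufficient_coverage`
#' rather than forced to a decision.
#'
#' @param counts A tibble with `marker_id`, `alt_reads`, `total_reads`
#'   (and optionally `sample_id`), typically from [pool_replicates()].
#' @param profiles Optional [estimate_error_profile()] output supplying
#'   per-marker `lod_pct`; markers present in `counts` must be resolvable
#'   here when given. `NULL` applies the global cutoff alone.
#' @param global_cutoff_pct Global VAF cutoff in percent (default 0.01).
#' @param min_coverage Minimum total reads for a conclusive call
#'   (default 10,000: one expected read at 0.01\% VAF).
#' @return The input tibble plus `vaf_pct`, `cutoff_pct` and `status`
#'   (`"positive"`, `"wild_type"` or `"insufficient_coverage"`).
#' @export
call_marker <- function(counts, profiles = NULL, global_cutoff_pct = 0.01,
                        min_coverage = 10000) {
  if (!is.null(profiles)) {
    unknown <- setdiff(counts$marker_id, profiles$marker_id)
    if (length(unknown)) {
      rlang::abort(paste0("No error profile for marker(s): ",
                          paste(unknown, collapse = ", ")),
                   class = "mrdcall_lookup_error")
    }
    counts <- dplyr::left_join(counts,
                               profiles[, c("marker_id", "lod_pct")],
                               by = "marker_id")
  } else {
    counts$lod_pct <- 0
  }
  counts |>
    dplyr::mutate(
      vaf_pct = dplyr::if_else(.data$total_reads > 0,
                               100 * .data$alt_reads / .data$total_reads,
                               NA_real_),
      cutoff_pct = pmax(global_cutoff_pct, .data$lod_pct),
      status = dplyr::case_when(
        .data$total_reads < min_coverage ~ "insufficient_coverage",
        .data$vaf_pct >= .data$cutoff_pct ~ "positive",
        TRUE ~ "wild_type"
      )
    ) |>
    dplyr::select(-"lod_pct")
}

#' Combine per-marker calls into sample-level ctDNA status
#'
#' A sample is ctDNA-positive if any of its 1-3 tumor-informed markers is
#' positive (the sensitivity-maximising rule for multi-marker monitoring),
#' inconclusive if every marker lacked coverage, and wild type otherwise.
#'
#' @param marker_calls Output of [call_marker()], with a `sample_id`
#'   column (a single implicit sample is assumed if absent).
#' @return A tibble with one row per sample: `sample_id`, `n_markers`,
#'   `n_positive`, `sample_status`.
#' @export
call_sample <- function(marker_calls) {
  if (nrow(marker_calls) < 1) {
    rlang::abort("Need at least one marker call.",
                 class = "mrdcall_input_error")
  }
  if (!"sample_id" %in% names(marker_calls)) {
    marker_calls$sample_id <- "sample"
  }
  marker_calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      n_positive = sum(.data$status == "positive"),
      sample_status = dplyr::case_when(
        any(.data$status == "positive") ~ "positive",
        all(.data$status == "insufficient_coverage") ~ "inconclusive",
        TRUE ~ "wild_type"
      ),
      .groups = "drop"
    )
}

#' Read and write count and call tables
#'
#' Tab-delimited glue for the pipeline: count tables carry `sample_id`,
#' `marker_id`, `replicate`, `alt_reads`, `total_reads`; call tables add
#' `vaf_pct`, `cutoff_pct`, `status`. VAF columns are written with enough
#' digits to distinguish 0.0001\% steps.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return `read_counts_tsv()` returns a tibble; the writers return their
#'   input invisibly.
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("marker_id", "alt_reads", "total_reads")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    rlang::abort(paste0("Count table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mrdcall_format_error")
  }
  if (any(x$alt_reads < 0 | x$alt_reads > x$total_reads)) {
    rlang::abort("Count table violates 0 <= alt_reads <= total_reads.",
                 class = "mrdcall_format_error")
  }
  x
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname read_counts_tsv
#' @export
write_calls_tsv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::any_of(c("vaf_pct", "cutoff_pct")),
    ~ formatC(.x, format = "f", digits = 6)))
  readr::write_tsv(x, path)
  invisible(x)
}
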