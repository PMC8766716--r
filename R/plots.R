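#' Plot a dilution-series linearity fit
#'
#' Observed versus expected VAF on log10 axes with the fitted line and the
#' identity for reference.
#'
#' @param object An `mrd_linearity` object from [linearity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrd_linearity <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$expected_vaf_pct,
                               y = .data$observed_vaf_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Expected VAF [%]", y = "Observed VAF [%]",
                  title = sprintf("Dilution linearity (r² = %.4f)",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a longitudinal patient ctDNA trajectory
#'
#' VAF over days since resection on a log axis, with the calling cutoff
#' and (optionally) the imaging-based relapse day marked. Measurements
#' below the cutoff are drawn hollow.
#'
#' @param series A tibble with `day`, `alt_reads`, `total_reads` (pooled
#'   or per replicate; replicates are pooled per day before plotting).
#' @param cutoff_pct VAF cutoff line in percent (default 0.01).
#' @param imaging_day Optional imaging relapse day to mark.
#' @return A ggplot object.
#' @export
plot_patient_series <- function(series, cutoff_pct = 0.01,
                                imaging_day = NULL) {
  if (!"marker_id" %in% names(series)) series$marker_id <- "marker"
  pooled <- series |>
    dplyr::mutate(sample_id = as.character(.data$day)) |>
    pool_replicates() |>
    dplyr::mutate(day = as.integer(.data$sample_id),
                  vaf_pct = 100 * .data$alt_reads / .data$total_reads,
                  detected = .data$vaf_pct >= cutoff_pct)
  floor_pct <- cutoff_pct / 10
  p <- ggplot2::ggplot(pooled,
                       ggplot2::aes(x = .data$day,
                                    y = pmax(.data$vaf_pct, floor_pct),
                                    group = .data$marker_id)) +
    ggplot2::geom_hline(yintercept = cutoff_pct, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$detected), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "Above cutoff") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Days since resection", y = "VAF [%]") +
    ggplot2::theme_minimal()
  if (!is.null(imaging_day)) {
    p <- p + ggplot2::geom_vline(xintercept = imaging_day,
                                 linetype = "dotted")
  }
  p
}

#' Plot detection power against input mass or VAF
#'
#' Analytic template-presence probability (line) and simulated detection
#' fraction (points) from rows of [detection_power()] output.
#'
#' @param power A tibble of [detection_power()] rows.
#' @param x One of `"input_mass_ng"`, `"true_vaf_pct"`, `"replicates"`:
#'   the abscissa.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(power, x = "input_mass_ng") {
  x <- match.arg(x, c("input_mass_ng", "true_vaf_pct", "replicates"))
  ggplot2::ggplot(power, ggplot2::aes(x = .data[[x]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_template,
                                    colour = "analytic (template present)")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_detect,
                                     colour = "simulated (called positive)"),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c("analytic (template present)" = "grey40",
                                            "simulated (called positive)" = "steelblue"),
                                 name = NULL) +
    ggplot2::labs(x = x, y = "Detection probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
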