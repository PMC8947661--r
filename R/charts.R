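#' Baseline series for one monitored control analyte
#'
#' Ordered values of one positive-control analyte over the baseline runs
#' (e.g. seven consecutive days), from which Levey-Jennings QC limits are
#' derived.
#'
#' @param analyte_id the monitored analyte (e.g. a fusion transcript or an
#'   amplified gene).
#' @param kind `"fusion_reads"` (internal-control-normalized fusion reads)
#'   or `"cna_fold_change"`.
#' @param values numeric vector, one value per baseline run.
#' @param run_dates optional labels, same length as `values`.
#' @return an object of class `control_series`.
#' @export
control_series <- function(analyte_id, kind = c("fusion_reads",
                                                "cna_fold_change"),
                           values, run_dates = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(analyte_id), length(analyte_id) == 1L,
            is.numeric(values), all(is.finite(values)))
  if (!is.null(run_dates) && length(run_dates) != length(values)) {
    stop("control_series: run_dates must match values in length")
  }
  structure(list(analyte_id = analyte_id, kind = kind,
                 values = as.numeric(values),
                 run_dates = run_dates %||% paste0("run", seq_along(values))),
            class = "control_series")
}

#' Normalize fusion reads to the internal process controls
#'
#' Divides a fusion read/molecular count by the arithmetic mean of the four
#' internal process-control counts (TBP, HMBS, MET E6-E7, MET E11-E12),
#' optionally rescaled by a constant. This is the quantity monitored on the
#' fusion control charts.
#'
#' @param fusion_reads nonnegative count.
#' @param controls an [internal_controls()] panel; at least one count must
#'   be positive.
#' @param scale multiplicative rescaling constant (default 1).
#' @return numeric scalar.
#' @export
#' @examples
#' normalize_to_internal_controls(400, internal_controls(100, 100, 100, 100))
normalize_to_internal_controls <- function(fusion_reads, controls, scale = 1) {
  stopifnot(is_scalar_num(fusion_reads), fusion_reads >= 0,
            inherits(controls, "internal_control_panel"),
            is_scalar_num(scale), scale > 0)
  m <- mean(c(controls$tbp, controls$hmbs, controls$met_e6_e7,
              controls$met_e11_e12))
  if (m <= 0) {
    stop("normalize_to_internal_controls: undefined normalization, all four internal controls are zero")
  }
  fusion_reads / m * scale
}

#' Derive Levey-Jennings QC limits from a baseline series
#'
#' Limits are the baseline mean plus/minus three sample standard
#' deviations (n - 1 denominator). The lower limit is not floored at zero
#' unless requested.
#'
#' @param series a [control_series()] with at least two values.
#' @param floor_at_zero if `TRUE`, a negative lower limit is raised to 0.
#' @return an object of class `control_limits`: `analyte_id`, `mean`,
#'   `sd`, `lower`, `upper`.
#' @export
#' @examples
#' derive_limits(control_series("CCDC6-RET", "fusion_reads", c(10, 10, 10)))
derive_limits <- function(series, floor_at_zero = FALSE) {
  stopifnot(inherits(series, "control_series"))
  if (length(series$values) < 2L) {
    stop("derive_limits: insufficient baseline, need >= 2 values")
  }
  m <- mean(series$values)
  s <- stats::sd(series$values)
  lower <- m - 3 * s
  if (floor_at_zero) lower <- max(lower, 0)
  structure(list(analyte_id = series$analyte_id, mean = m, sd = s,
                 lower = lower, upper = m + 3 * s),
            class = "control_limits")
}

#' Control limits from explicit bounds
#'
#' Builds a `control_limits` object from a known range (e.g. one of the
#' assay's established QC ranges), back-solving mean and SD.
#'
#' @param analyte_id the monitored analyte.
#' @param lower,upper the range bounds (`upper >= lower`).
#' @return an object of class `control_limits`.
#' @export
control_limits_from_range <- function(analyte_id, lower, upper) {
  stopifnot(is_scalar_num(lower), is_scalar_num(upper), upper >= lower)
  structure(list(analyte_id = analyte_id, mean = (lower + upper) / 2,
                 sd = (upper - lower) / 6, lower = lower, upper = upper),
            class = "control_limits")
}

#' Classify a control point against QC limits
#'
#' Containment is closed-interval: a value exactly at a limit is in
#' control.
#'
#' @param value numeric vector of control measurements.
#' @param limits a `control_limits` object.
#' @return character vector in `{"in_control", "out_of_control_low",
#'   "out_of_control_high"}`.
#' @export
evaluate_point <- function(value, limits) {
  stopifnot(inherits(limits, "control_limits"), is.numeric(value),
            limits$upper >= limits$lower)
  ifelse(value < limits$lower, "out_of_control_low",
         ifelse(value > limits$upper, "out_of_control_high", "in_control"))
}

#' Recover baseline mean and SD from QC limits
#'
#' Inverts [derive_limits()]: `mean = (lower + upper) / 2`,
#' `sd = (upper - lower) / 6`.
#'
#' @param limits a `control_limits` object (or anything with `lower`,
#'   `upper`).
#' @return list with `mean` and `sd`.
#' @export
#' @examples
#' recover_mean_sd(control_limits_from_range("CCDC6-RET", 525, 2605))
recover_mean_sd <- function(limits) {
  stopifnot(is_scalar_num(limits$lower), is_scalar_num(limits$upper),
            limits$upper >= limits$lower)
  list(mean = (limits$lower + limits$upper) / 2,
       sd = (limits$upper - limits$lower) / 6)
}

#' Established QC ranges of the batch positive-control analytes
#'
#' The assay's validated plus/minus 3 SD control-chart ranges for the
#' three monitored fusion transcripts (internal-control-normalized reads)
#' and the two monitored amplifications (fold change).
#'
#' @return data frame with columns `analyte_id`, `kind`, `lower`, `upper`.
#' @export
reference_control_limits <- function() {
  data.frame(
    analyte_id = c("CCDC6-RET", "EML4-ALK", "CD74-ROS1", "ERBB2", "MYC"),
    kind = c("fusion_reads", "fusion_reads", "fusion_reads",
             "cna_fold_change", "cna_fold_change"),
    lower = c(525, 2880, 276, 2.14, 1.73),
    upper = c(2605, 7474, 1671, 3.77, 3.18),
    stringsAsFactors = FALSE
  )
}

#' Plot a Levey-Jennings control chart
#'
#' Base-graphics chart of one analyte's values against its mean and
#' plus/minus 3 SD limits.
#'
#' @param series a [control_series()].
#' @param limits a `control_limits` object (derived from the series when
#'   omitted).
#' @param file optional PNG path; when given the chart is written there.
#' @param ... passed to [graphics::plot()].
#' @return the limits, invisibly.
#' @export
plot_control_chart <- function(series, limits = derive_limits(series),
                               file = NULL, ...) {
  draw <- function() {
    n <- length(series$values)
    ylim <- range(series$values, limits$lower, limits$upper)
    graphics::plot(seq_len(n), series$values, type = "b", pch = 19,
                   xlab = "run", ylab = series$kind,
                   main = series$analyte_id, ylim = ylim, ...)
    graphics::abline(h = limits$mean, lty = 1)
    graphics::abline(h = c(limits$lower, limits$upper), lty = 2, col = 2)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(limits)
}
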