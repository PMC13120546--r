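## Force Symmetry Index (Robinson symmetry metric) and cohort summaries.

#' Force Symmetry Index of a bilateral force pair
#'
#' The Robinson symmetry metric `FSI = |F_R - F_L| / (F_R + F_L)`:
#' 0 is perfect left/right symmetry, 1 total asymmetry (all load on one
#' side).  Symmetric in its arguments and invariant to rescaling both
#' forces by a common positive factor.
#'
#' @param f_right,f_left non-negative forces (newtons); vectorized.
#' @return FSI values in \[0, 1\].
#' @export
compute_fsi <- function(f_right, f_left) {
  if (any(f_right < 0) || any(f_left < 0)) {
    stop("forces must be non-negative", call. = FALSE)
  }
  total <- f_right + f_left
  if (any(total == 0)) {
    stop("FSI undefined when both forces are zero", call. = FALSE)
  }
  abs(f_right - f_left) / total
}

#' Session-level FSI from a bilateral force stream
#'
#' One FSI value per recorded session: the FSI of the session-mean left and
#' right forces over the stable-walking window.  Samples where both
#' channels fall below `contact_floor_n` simultaneously are treated as
#' non-contact and excluded (the index is undefined at zero total load).
#'
#' @param stream data.frame with columns `f_right_n`, `f_left_n` (as written
#'   by [generate_force_pair()]).
#' @param contact_floor_n non-contact exclusion floor, newtons.
#' @return a single FSI value.
#' @export
session_fsi <- function(stream, contact_floor_n = 0.5) {
  stream <- as.data.frame(stream)
  if (nrow(stream) == 0) stop("empty force stream", call. = FALSE)
  stopifnot(all(c("f_right_n", "f_left_n") %in% names(stream)))
  keep <- !(stream$f_right_n < contact_floor_n & stream$f_left_n < contact_floor_n)
  if (!any(keep)) {
    stop("no samples with positive total force: session FSI undefined",
         call. = FALSE)
  }
  compute_fsi(mean(stream$f_right_n[keep]), mean(stream$f_left_n[keep]))
}

#' Percentage improvement in FSI between baseline and end of program
#'
#' `100 * (fsi_day1 - fsi_day15) / fsi_day1`: the relative reduction in
#' asymmetry, positive when symmetry improved.
#'
#' @param fsi_day1 baseline FSI (> 0); vectorized.
#' @param fsi_day15 end-of-program FSI.
#' @return improvement in percent (unrounded; reports round half-up to 2
#'   decimals).
#' @export
improvement_percent <- function(fsi_day1, fsi_day15) {
  if (any(fsi_day1 <= 0)) {
    stop("improvement undefined for a zero baseline FSI", call. = FALSE)
  }
  100 * (fsi_day1 - fsi_day15) / fsi_day1
}

#' Cohort summary of baseline/end FSI pairs
#'
#' @param rows data.frame with columns `subject_id` (optional), `day1`,
#'   `day15`: one row per subject.
#' @return an object of class `cohort_summary`: a list with
#'   `mean_fsi_day1`, `mean_fsi_day15`, `mean_improvement_pct` (arithmetic
#'   means) and `per_subject` (data.frame with unrounded `improvement_pct`).
#' @export
cohort_summary <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("cohort summary needs at least one row", call. = FALSE)
  stopifnot(all(c("day1", "day15") %in% names(rows)))
  if (is.null(rows$subject_id)) {
    rows$subject_id <- sprintf("Subject %d", seq_len(nrow(rows)))
  }
  imp <- improvement_percent(rows$day1, rows$day15)
  per_subject <- data.frame(subject_id = rows$subject_id,
                            day1 = rows$day1, day15 = rows$day15,
                            improvement_pct = imp,
                            stringsAsFactors = FALSE)
  structure(
    list(mean_fsi_day1 = mean(rows$day1),
         mean_fsi_day15 = mean(rows$day15),
         mean_improvement_pct = mean(imp),
         per_subject = per_subject),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort FSI summary (", nrow(x$per_subject), " subjects)\n", sep = "")
  tab <- x$per_subject
  tab$day1 <- sprintf("%.4f", round_half_up(tab$day1, 4))
  tab$day15 <- sprintf("%.4f", round_half_up(tab$day15, 4))
  tab$improvement_pct <- sprintf("%.2f%%", round_half_up(tab$improvement_pct, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Mean:  Day 1 %.4f   Day 15 %.4f   Improvement %.2f%%\n",
              round_half_up(x$mean_fsi_day1, 4),
              round_half_up(x$mean_fsi_day15, 4),
              round_half_up(x$mean_improvement_pct, 2)))
  invisible(x)
}

#' Per-day interlimb channel difference
#'
#' Mean signed right-minus-left channel difference for each day, the
#' longitudinal convergence measure for the two handlebar sensors.
#'
#' @param daily data.frame with a `day` column plus the two channel columns.
#' @param right,left channel column names (defaults use the true-force
#'   columns; pass `adc_right` / `adc_left` for raw counts).
#' @return data.frame with columns `day` and `mean_diff` (sign preserved).
#' @export
interlimb_voltage_difference <- function(daily, right = "f_right_n",
                                         left = "f_left_n") {
  daily <- as.data.frame(daily)
  if (nrow(daily) == 0) stop("empty stream", call. = FALSE)
  stopifnot(all(c("day", right, left) %in% names(daily)))
  diffs <- daily[[right]] - daily[[left]]
  agg <- tapply(diffs, daily$day, mean)
  data.frame(day = as.numeric(names(agg)), mean_diff = as.numeric(agg))
}

#' Force-sensor calibration curve from reference loads
#'
#' @param reference_loads strictly increasing known loads, newtons.
#' @param adc_readings ADC counts observed at those loads (same length,
#'   each in \[0, 1023\]).
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(reference_loads, adc_readings) {
  if (length(reference_loads) != length(adc_readings) ||
      length(reference_loads) < 2) {
    stop("need >= 2 calibration points with matching lengths", call. = FALSE)
  }
  if (is.unsorted(reference_loads, strictly = TRUE)) {
    stop("reference loads must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(adc_readings, strictly = TRUE)) {
    stop("ADC readings must be strictly increasing with load", call. = FALSE)
  }
  if (any(adc_readings < 0 | adc_readings > 1023)) {
    stop("ADC readings must lie in [0, 1023]", call. = FALSE)
  }
  structure(list(reference_loads = reference_loads,
                 adc_readings = adc_readings),
            class = "calibration_curve")
}

#' Default linear calibration used by the generator's ADC mapping
#' @return a [calibration_curve()] mapping 0--100 N onto 0--1023 counts.
#' @export
default_calibration <- function() {
  calibration_curve(reference_loads = c(0, 25, 50, 75, 100),
                    adc_readings = c(0, 256, 512, 767, 1023))
}

#' Convert ADC counts to force through a calibration curve
#'
#' Piecewise-linear interpolation through the calibration points, with
#' clamped (constant) extrapolation beyond the first and last knots.
#'
#' @param adc counts in \[0, 1023\]; vectorized.
#' @param curve a [calibration_curve()].
#' @return forces in newtons.
#' @export
adc_to_force <- function(adc, curve = default_calibration()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(adc < 0 | adc > 1023)) {
    stop("ADC counts must lie in [0, 1023]", call. = FALSE)
  }
  stats::approx(x = curve$adc_readings, y = curve$reference_loads,
                xout = adc, rule = 2)$y
}
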