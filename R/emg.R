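## sEMG conditioning chain and longitudinal amplitude statistics.

#' Construct a surface EMG record
#'
#' @param samples_mv signal in millivolts.
#' @param fs sampling rate, Hz (> 1000 so the 500 Hz band edge is below
#'   Nyquist).
#' @param subject_id,day provenance.
#' @param stage processing stage; records advance only raw -> filtered ->
#'   denoised.
#' @return an object of class `emg_record`.
#' @export
emg_record <- function(samples_mv, fs, subject_id = "S1", day = 1L,
                       stage = c("raw", "filtered", "denoised")) {
  stage <- match.arg(stage)
  if (fs <= 1000) stop("fs must exceed 1000 Hz", call. = FALSE)
  if (!is.numeric(samples_mv) || length(samples_mv) == 0) {
    stop("samples_mv must be a non-empty numeric vector", call. = FALSE)
  }
  structure(list(samples_mv = as.numeric(samples_mv), fs = fs,
                 subject_id = subject_id, day = as.integer(day),
                 stage = stage),
            class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record %s day %d: %d samples @ %g Hz, stage %s>\n",
              x$subject_id, x$day, length(x$samples_mv), x$fs, x$stage))
  invisible(x)
}

#' Band-pass filter specification
#'
#' Defaults to the 30--500 Hz surface-EMG band with an overall 4th-order
#' Butterworth response (a 2nd-order band-pass section, which has filter
#' order 4), applied forward-backward for zero phase.
#'
#' @param low_cut_hz,high_cut_hz band edges, Hz.
#' @param order overall filter order (even; the band-pass section order is
#'   `order / 2`).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut_hz = 30, high_cut_hz = 500, order = 4) {
  if (!(low_cut_hz > 0 && high_cut_hz > low_cut_hz)) {
    stop("need 0 < low_cut_hz < high_cut_hz", call. = FALSE)
  }
  if (order < 2 || order %% 2 != 0) {
    stop("order must be a positive even integer", call. = FALSE)
  }
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filtering of an EMG record
#'
#' Removes low-frequency drift (below the low cut) and high-frequency noise
#' (above the high cut) with a Butterworth band-pass applied
#' forward-backward (zero phase, no waveform delay).  Length is preserved
#' and the record advances to stage `"filtered"`.
#'
#' @param record an [emg_record()] at stage `"raw"`.
#' @param spec a [filter_spec()].
#' @return the filtered `emg_record`.
#' @export
bandpass_filter <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "emg_record"), inherits(spec, "filter_spec"))
  if (record$stage != "raw") {
    stop("bandpass_filter expects a raw record (stages advance raw -> filtered -> denoised)",
         call. = FALSE)
  }
  nyq <- record$fs / 2
  if (spec$high_cut_hz >= nyq) {
    stop(sprintf(paste0("high_cut_hz (%g) must be below Nyquist (%g); ",
                        "raise fs or lower the band edge"),
                 spec$high_cut_hz, nyq), call. = FALSE)
  }
  bw <- signal::butter(spec$order / 2,
                       c(spec$low_cut_hz, spec$high_cut_hz) / nyq,
                       type = "pass")
  filtered <- signal::filtfilt(bw, record$samples_mv)
  out <- record
  out$samples_mv <- filtered
  out$stage <- "filtered"
  out
}

#' Wavelet denoising of a filtered EMG record
#'
#' Daubechies db4 decomposition over `levels` dyadic levels, soft
#' thresholding of the detail coefficients at the universal threshold
#' `sigma * sqrt(2 log N)` with `sigma` estimated from the median absolute
#' deviation of the finest-level details (`MAD / 0.6745`), then exact
#' reconstruction.  The signal is reflect-padded to a multiple of
#' `2^levels` internally and trimmed after reconstruction, so length is
#' preserved.  The record advances to stage `"denoised"`.
#'
#' @param record an [emg_record()] at stage `"filtered"`.
#' @param levels decomposition depth (default 4).
#' @return the denoised `emg_record`.
#' @export
wavelet_denoise <- function(record, levels = 4) {
  stopifnot(inherits(record, "emg_record"))
  if (record$stage != "filtered") {
    stop("wavelet_denoise expects a filtered record", call. = FALSE)
  }
  x <- record$samples_mv
  n <- length(x)
  block <- 2^levels
  if (n < 4 * block) {
    stop(sprintf("signal too short for a %d-level decomposition (need >= %d samples)",
                 levels, 4 * block), call. = FALSE)
  }
  pad <- (block - n %% block) %% block
  if (pad > 0) x <- c(x, rev(x)[seq_len(pad)])   # reflect-pad the tail
  dec <- dwt_db4(x, levels)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  y <- idwt_db4(dec)[seq_len(n)]
  out <- record
  out$samples_mv <- y
  out$stage <- "denoised"
  out
}

#' Mean rectified EMG amplitude
#'
#' Mean of the absolute signal value over the record, the longitudinal
#' activation metric compared across program days.
#'
#' @param record an [emg_record()] at stage `"denoised"`.
#' @return amplitude in millivolts.
#' @export
mean_amplitude <- function(record) {
  stopifnot(inherits(record, "emg_record"))
  if (record$stage != "denoised") {
    stop("mean_amplitude expects a denoised record", call. = FALSE)
  }
  if (length(record$samples_mv) == 0) stop("empty signal", call. = FALSE)
  mean(abs(record$samples_mv))
}

#' Root-mean-square EMG amplitude (secondary metric)
#' @inheritParams mean_amplitude
#' @return RMS amplitude in millivolts.
#' @export
rms_amplitude <- function(record) {
  stopifnot(inherits(record, "emg_record"))
  if (record$stage != "denoised") {
    stop("rms_amplitude expects a denoised record", call. = FALSE)
  }
  sqrt(mean(record$samples_mv^2))
}

#' Paired t-test between baseline and end-of-program amplitudes
#'
#' Classical paired test on per-subject differences `d = day15 - day1`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value.
#'
#' @param day1_values,day15_values equal-length per-subject amplitude
#'   vectors (mV), n >= 2.
#' @return an object of class `paired_test` with elements `t_statistic`,
#'   `df`, `p_value`, `mean_day1_mv`, `mean_day15_mv`, `delta_mv`.
#' @export
paired_ttest <- function(day1_values, day15_values) {
  n <- length(day1_values)
  if (length(day15_values) != n) {
    stop("day 1 and day 15 vectors must have equal length", call. = FALSE)
  }
  if (n < 2) stop("paired test needs n >= 2", call. = FALSE)
  d <- day15_values - day1_values
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("zero-variance differences: paired test degenerate", call. = FALSE)
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1L
  structure(
    list(t_statistic = t_stat, df = df,
         p_value = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
         mean_day1_mv = mean(day1_values),
         mean_day15_mv = mean(day15_values),
         delta_mv = mean(day15_values) - mean(day1_values)),
    class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.3g,  delta = %.3f mV (%.3f -> %.3f)\n",
              x$df, x$t_statistic, x$p_value, x$delta_mv,
              x$mean_day1_mv, x$mean_day15_mv))
  invisible(x)
}

#' Normal quantile-quantile pairs
#'
#' Sorted data paired with standard-normal quantiles at plotting positions
#' `(i - 0.5) / n`, the raw material of a Q-Q normality check.
#'
#' @param values numeric vector, n >= 3.
#' @return data.frame with columns `theoretical` and `empirical`.
#' @export
normality_qq <- function(values) {
  n <- length(values)
  if (n < 3) stop("Q-Q pairs need n >= 3", call. = FALSE)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             empirical = sort(values))
}
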