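## Closed-loop vibrotactile feedback simulation.

#' Vibrotactile feedback configuration
#'
#' Actuation parameters of the handle-mounted vibration motors plus the
#' latency contract of the closed loop.  The 100 Hz / 1.5 g / 300 ms pulse
#' is carried as metadata; the simulator enforces the pulse duration (as the
#' per-side refractory window) and the latency bound.
#'
#' @param vibration_frequency_hz motor drive frequency (metadata).
#' @param amplitude_g motor amplitude in g-units (metadata).
#' @param duration_ms pulse duration; a side cannot retrigger while its
#'   pulse window is open.
#' @param max_latency_ms upper bound on loop latency; the simulated
#'   actuation latency must stay below it.
#' @param actuation_latency_ms simulated detection-to-actuation latency.
#' @param trigger_mode `"fsi"` triggers on the per-sample normalized
#'   asymmetry (Robinson index); `"raw_difference"` on the absolute force
#'   difference in newtons.
#' @return an object of class `haptic_config`.
#' @export
haptic_config <- function(vibration_frequency_hz = 100, amplitude_g = 1.5,
                          duration_ms = 300, max_latency_ms = 120,
                          actuation_latency_ms = 50,
                          trigger_mode = c("fsi", "raw_difference")) {
  trigger_mode <- match.arg(trigger_mode)
  vals <- c(vibration_frequency_hz, amplitude_g, duration_ms, max_latency_ms,
            actuation_latency_ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all haptic parameters must be positive", call. = FALSE)
  }
  if (actuation_latency_ms > max_latency_ms) {
    stop("actuation latency exceeds the configured latency bound",
         call. = FALSE)
  }
  structure(list(vibration_frequency_hz = vibration_frequency_hz,
                 amplitude_g = amplitude_g, duration_ms = duration_ms,
                 max_latency_ms = max_latency_ms,
                 actuation_latency_ms = actuation_latency_ms,
                 trigger_mode = trigger_mode),
            class = "haptic_config")
}

#' Calibrate the asymmetry trigger threshold
#'
#' The threshold is the arithmetic mean of asymmetry values observed under
#' varying load conditions during calibration trials.
#'
#' @param asymmetry_samples asymmetry values, each in \[0, 1\].
#' @return an object of class `threshold_calibration` with elements
#'   `samples` and `threshold`.
#' @export
calibrate_threshold <- function(asymmetry_samples) {
  if (length(asymmetry_samples) == 0) {
    stop("calibration needs at least one asymmetry sample", call. = FALSE)
  }
  if (any(!is.finite(asymmetry_samples)) ||
      any(asymmetry_samples < 0 | asymmetry_samples > 1)) {
    stop("asymmetry samples must lie in [0, 1]", call. = FALSE)
  }
  structure(list(samples = asymmetry_samples,
                 threshold = mean(asymmetry_samples)),
            class = "threshold_calibration")
}

#' Default shipped asymmetry threshold
#'
#' Reproduces the calibration protocol on synthetic data: five calibration
#' subjects, 100 asymmetry instances each under varying load conditions
#' (per-sample FSI of noisy moderate-asymmetry force pairs), averaged via
#' [calibrate_threshold()].  Seeded and deterministic.
#'
#' @param seed master seed for the calibration draws.
#' @return the calibrated threshold (single number in (0, 1)).
#' @export
default_asymmetry_threshold <- function(seed = 20) {
  samples <- unlist(lapply(1:5, function(subj) {
    with_seed(derive_seed(seed, sprintf("calibration/subject%d", subj)), {
      total <- stats::runif(100, 30, 80)            # varying load, newtons
      s <- stats::rbeta(100, 2, 6)                  # typical walking asymmetry
      f_r <- total * (1 + s) / 2 + rnorm(100, 0, 0.5)
      f_l <- total * (1 - s) / 2 + rnorm(100, 0, 0.5)
      compute_fsi(pmax(f_r, 0), pmax(f_l, 0))
    })
  }))
  calibrate_threshold(pmin(1, pmax(0, samples)))$threshold
}

#' Scan a force stream and emit haptic feedback events
#'
#' Walks the stream in time order; when the per-sample trigger statistic
#' exceeds `threshold` and the side bearing the greater force is not inside
#' an open pulse window, a feedback event opens on that (heavier) side --
#' cueing the user to unload it.  The side stays refractory for the pulse
#' duration.  The simulated actuation onset lags the threshold-crossing
#' sample by the configured actuation latency, which must respect the
#' latency bound.
#'
#' @param stream a force stream (columns `timestamp_s`, `f_right_n`,
#'   `f_left_n`), time-ordered.
#' @param threshold trigger threshold in (0, 1) for `"fsi"` mode, newtons
#'   for `"raw_difference"` mode.
#' @param config a [haptic_config()].
#' @param contact_floor_n samples with both channels below this floor are
#'   non-contact and never trigger.
#' @return data.frame of class `feedback_log`: columns `onset_s` (threshold
#'   crossing), `actuation_s`, `side`, `duration_ms`,
#'   `triggering_asymmetry`.
#' @export
run_feedback <- function(stream, threshold, config = haptic_config(),
                         contact_floor_n = 0.5) {
  stopifnot(inherits(config, "haptic_config"))
  stream <- as.data.frame(stream)
  stopifnot(all(c("timestamp_s", "f_right_n", "f_left_n") %in% names(stream)))
  assert_time_ordered(stream$timestamp_s, "force stream")
  if (config$trigger_mode == "fsi" && !(threshold > 0 && threshold < 1)) {
    stop("FSI-mode threshold must lie in (0, 1)", call. = FALSE)
  }
  t <- stream$timestamp_s
  fr <- stream$f_right_n
  fl <- stream$f_left_n
  contact <- !(fr < contact_floor_n & fl < contact_floor_n)
  total <- fr + fl
  stat <- if (config$trigger_mode == "fsi") {
    ifelse(total > 0, abs(fr - fl) / total, 0)
  } else {
    abs(fr - fl)
  }
  hot <- contact & stat > threshold
  side <- ifelse(fr >= fl, "right", "left")
  dur_s <- config$duration_ms / 1000
  open_until <- c(right = -Inf, left = -Inf)
  events <- vector("list", 0L)
  for (i in which(hot)) {
    s <- side[i]
    if (t[i] >= open_until[[s]]) {
      events[[length(events) + 1L]] <- data.frame(
        onset_s = t[i],
        actuation_s = t[i] + config$actuation_latency_ms / 1000,
        side = s, duration_ms = config$duration_ms,
        triggering_asymmetry = stat[i], stringsAsFactors = FALSE)
      open_until[[s]] <- t[i] + dur_s
    }
  }
  out <- if (length(events)) do.call(rbind, events) else {
    data.frame(onset_s = numeric(0), actuation_s = numeric(0),
               side = character(0), duration_ms = numeric(0),
               triggering_asymmetry = numeric(0), stringsAsFactors = FALSE)
  }
  structure(out, threshold = threshold, trigger_mode = config$trigger_mode,
            class = c("feedback_log", "data.frame"))
}
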