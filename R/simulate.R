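## Synthetic multimodal sensor generator.
##
## Every generator derives a per-stream sub-seed from the cohort master seed
## (subject/day/modality key), so streams are individually reproducible and
## regenerating one never shifts another.

ADC_MAX <- 1023L
ADC_FULL_SCALE_N <- 100   # default linear force-to-ADC mapping: 100 N -> 1023
GAIT_MODULATION_HZ <- 1.0 # within-session load modulation (one gait cycle/s)
GAIT_MODULATION_DEPTH <- 0.3

#' Interpolate a subject's target FSI for a (possibly fractional) day
#'
#' Exponential recovery interpolates geometrically between the Day-1 and
#' final-day FSI (a constant-rate relative decay, matching the smooth
#' monotone decline seen in rehabilitation trajectories); linear recovery
#' interpolates arithmetically.  Both hit the two endpoints exactly.
#'
#' @param profile a [subject_profile()].
#' @param day day in `[1, n_days]`; fractional values sample the continuous
#'   underlying recovery curve.
#' @param n_days program length.
#' @return the target FSI, in \[0, 1\].
#' @export
interpolate_fsi <- function(profile, day, n_days = 15) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(day < 1 | day > n_days)) {
    stop(sprintf("day must lie in [1, %d]", n_days), call. = FALSE)
  }
  frac <- (day - 1) / (n_days - 1)
  f1 <- profile$fsi_day1
  f15 <- profile$fsi_day15
  if (profile$recovery_shape == "linear" || f1 == 0 || f15 == 0) {
    # geometric interpolation is undefined at a zero endpoint
    f1 + frac * (f15 - f1)
  } else {
    f1 * exp(log(f15 / f1) * frac)
  }
}

## map true force (N) to quantized ADC counts via the default linear scale
force_to_adc <- function(force_n) {
  as.integer(pmin(ADC_MAX, pmax(0L, round(force_n / ADC_FULL_SCALE_N * ADC_MAX))))
}

#' Generate one session of bilateral handlebar force samples
#'
#' Left/right channel means are set so that the FSI of the session-mean
#' forces equals the profile's interpolated target for `day` (right side
#' loaded heavier by convention).  Both channels share a common sinusoidal
#' gait-phase modulation, carry additive Gaussian sensor noise truncated at
#' zero, and are quantized to 10-bit ADC counts alongside the true forces.
#'
#' @param profile a [subject_profile()].
#' @param day integer day in `[1, config$n_days]`.
#' @param config a [cohort_config()].
#' @return a data.frame of class `force_stream` with columns `timestamp_s`,
#'   `adc_right`, `adc_left`, `f_right_n`, `f_left_n`; the generation target
#'   is attached as attribute `target_fsi`.
#' @export
generate_force_pair <- function(profile, day, config) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "cohort_config"))
  if (length(day) != 1L || day < 1 || day > config$n_days) {
    stop(sprintf("day must be a single value in [1, %d], got %s",
                 config$n_days, paste(day, collapse = ",")), call. = FALSE)
  }
  target <- interpolate_fsi(profile, day, config$n_days)
  n <- round(config$session_length_s * config$fs_force)
  t <- (seq_len(n) - 1) / config$fs_force
  m <- 1 + GAIT_MODULATION_DEPTH * sin(2 * pi * GAIT_MODULATION_HZ * t)
  amp_r <- profile$base_force_n * (1 + target) / 2
  amp_l <- profile$base_force_n * (1 - target) / 2
  seed <- derive_seed(config$seed,
                      sprintf("%s/day%02d/force", profile$subject_id, day))
  stream <- with_seed(seed, {
    f_r <- pmax(0, amp_r * m + rnorm(n, 0, config$noise_sd_force))
    f_l <- pmax(0, amp_l * m + rnorm(n, 0, config$noise_sd_force))
    data.frame(timestamp_s = t,
               adc_right = force_to_adc(f_r), adc_left = force_to_adc(f_l),
               f_right_n = f_r, f_left_n = f_l)
  })
  structure(stream, target_fsi = target, subject_id = profile$subject_id,
            day = day, class = c("force_stream", "data.frame"))
}

#' Generate one session of surface EMG
#'
#' The clean component is band-limited (30--500 Hz) Gaussian activity under
#' a gait-locked burst envelope, rescaled so its mean rectified amplitude
#' equals the day-interpolated target (linear interpolation between the
#' profile's Day-1 and final-day amplitudes).  Contamination is added on
#' top: a slow sinusoidal baseline drift (0.4 Hz, below the 5 Hz drift
#' band) and high-frequency interference (750 Hz tone, above 600 Hz).
#'
#' @param profile a [subject_profile()].
#' @param day integer day in `[1, config$n_days]`.
#' @param config a [cohort_config()]; `fs_emg` must exceed 1000 Hz.
#' @param drift_amplitude_mv amplitude of the low-frequency drift (mV).
#' @param hf_amplitude_mv amplitude of the high-frequency interference (mV).
#' @param duration_s record length; defaults to the session length.
#' @return an [emg_record()] at stage `"raw"`; the clean component is kept
#'   in attribute `clean_mv` so denoising performance can be scored, and the
#'   amplitude target in attribute `target_amplitude_mv`.
#' @export
generate_emg <- function(profile, day, config,
                         drift_amplitude_mv = 0.5, hf_amplitude_mv = 0.2,
                         duration_s = config$session_length_s) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "cohort_config"))
  if (length(day) != 1L || day < 1 || day > config$n_days) {
    stop(sprintf("day must be a single value in [1, %d]", config$n_days),
         call. = FALSE)
  }
  frac <- (day - 1) / (config$n_days - 1)
  target <- profile$emg_day1_mv + frac * (profile$emg_day15_mv - profile$emg_day1_mv)
  if (target <= 0) stop("EMG amplitude target must be positive", call. = FALSE)
  fs <- config$fs_emg
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  seed <- derive_seed(config$seed,
                      sprintf("%s/day%02d/emg", profile$subject_id, day))
  bp <- signal::butter(2, c(30, 500) / (fs / 2), type = "pass")
  shape <- signal::butter(2, c(60, 200) / (fs / 2), type = "pass")
  rec <- with_seed(seed, {
    # band-limited carrier with a realistic sEMG spectral shape: power
    # concentrated near 80-150 Hz, rolling off well before the band edges
    carrier <- signal::filtfilt(bp, signal::filtfilt(shape, rnorm(n)))
    env <- 0.25 + 0.75 * sin(pi * GAIT_MODULATION_HZ * t)^2
    clean <- carrier * env
    clean <- clean * (target / mean(abs(clean)))
    drift <- drift_amplitude_mv * sin(2 * pi * 0.4 * t + stats::runif(1, 0, 2 * pi))
    hf <- hf_amplitude_mv * sin(2 * pi * 750 * t + stats::runif(1, 0, 2 * pi))
    list(clean = clean, raw = clean + drift + hf)
  })
  out <- emg_record(rec$raw, fs = fs, subject_id = profile$subject_id,
                    day = day, stage = "raw")
  attr(out, "clean_mv") <- rec$clean
  attr(out, "target_amplitude_mv") <- target
  out
}

#' Programmed tilt angles for the three walker orientation states
#' @return named numeric vector of degrees.
#' @export
walker_state_angles <- function() c(upright = 0, inclined = 25, falling = 75)

#' Generate a tri-axial acceleration sequence through programmed states
#'
#' Produces a gravity-dominated signal whose tilt matches each state's
#' programmed angle (upright 0 deg, inclined 25 deg, falling 75 deg).  Each
#' falling episode opens with a short transient magnitude drop (0.3 g for
#' 0.3 s) mimicking the free-fall phase before impact.  Gaussian sensor
#' noise is added per axis.  Ground-truth state-transition times are
#' returned alongside the stream.
#'
#' @param states data.frame with columns `state` (one of `"upright"`,
#'   `"inclined"`, `"falling"`) and `duration_s` (> 0).
#' @param config a [cohort_config()] (supplies `fs_accel` and the master
#'   seed).
#' @param noise_sd_g per-axis Gaussian noise standard deviation, g-units.
#' @param stream_id character tag entering the sub-seed derivation.
#' @return list with `stream` (data.frame `timestamp_s`, `ax_g`, `ay_g`,
#'   `az_g`) and `transitions` (data.frame `time_s`, `state` giving the
#'   onset of every programmed segment, including the first at 0).
#' @export
generate_accel_sequence <- function(states, config, noise_sd_g = 0.02,
                                    stream_id = "accel") {
  stopifnot(inherits(config, "cohort_config"))
  states <- as.data.frame(states)
  if (nrow(states) == 0) stop("state list must be non-empty", call. = FALSE)
  if (!all(c("state", "duration_s") %in% names(states))) {
    stop("states needs columns `state` and `duration_s`", call. = FALSE)
  }
  if (any(states$duration_s <= 0)) {
    stop("all state durations must be positive", call. = FALSE)
  }
  angles <- walker_state_angles()
  if (!all(states$state %in% names(angles))) {
    stop("states must be one of upright/inclined/falling", call. = FALSE)
  }
  fs <- config$fs_accel
  onsets <- c(0, cumsum(states$duration_s))
  n_per <- round(states$duration_s * fs)
  seg_state <- rep(states$state, n_per)
  n <- length(seg_state)
  t <- (seq_len(n) - 1) / fs
  theta <- angles[seg_state] * pi / 180
  mag <- rep(1, n)
  # free-fall transient at each falling-episode onset
  seg_id <- rep(seq_len(nrow(states)), n_per)
  for (i in which(states$state == "falling")) {
    idx <- which(seg_id == i)
    drop_len <- min(length(idx), round(0.3 * fs))
    mag[idx[seq_len(drop_len)]] <- 0.3
  }
  seed <- derive_seed(config$seed, paste0(stream_id, "/accel"))
  stream <- with_seed(seed, {
    data.frame(
      timestamp_s = t,
      ax_g = mag * sin(theta) + rnorm(n, 0, noise_sd_g),
      ay_g = rnorm(n, 0, noise_sd_g),
      az_g = mag * cos(theta) + rnorm(n, 0, noise_sd_g))
  })
  list(stream = stream,
       transitions = data.frame(time_s = onsets[-length(onsets)],
                                state = states$state,
                                stringsAsFactors = FALSE))
}

#' Generate a stride-interval series
#'
#' Footfall peak times are `t_i = i * mean_stride_s + e_i` with
#' `e_i ~ N(0, jitter_sd_s^2)` i.i.d.; stride intervals are their successive
#' differences, so under jitter the interval variance is `2 * jitter_sd_s^2`
#' (the differencing doubles the jitter variance and induces lag-1
#' anticorrelation, as observed in timing-jitter gait models).
#'
#' @param cfg a [stride_group_config()].
#' @param subject_id identifier attached to the result.
#' @return a [stride_intervals()] object; peak times are kept in attribute
#'   `peak_times_s`.
#' @export
generate_stride_series <- function(cfg, subject_id = "S1") {
  stopifnot(inherits(cfg, "stride_group_config"))
  peaks <- with_seed(cfg$seed, {
    seq_len(cfg$n_strides) * cfg$mean_stride_s +
      rnorm(cfg$n_strides, 0, cfg$jitter_sd_s)
  })
  out <- stride_intervals(subject_id = subject_id, group = cfg$group,
                          intervals_s = diff(peaks))
  attr(out, "peak_times_s") <- peaks
  out
}

#' Cohort-mean longitudinal handlebar force trajectory
#'
#' Builds the pooled two-channel series used for trajectory modelling:
#' the program is sampled continuously in time (`epochs_per_day` one-second
#' epochs per day), each epoch value being the across-subject mean of the
#' epoch-averaged channel force.  Epoch averaging spans whole gait cycles,
#' so the within-session modulation cancels and the per-point noise is the
#' raw sensor noise attenuated by the epoch and cohort averaging.
#'
#' @param config a [cohort_config()].
#' @param epochs_per_day epochs per day (default 80, giving 1200 points for
#'   the 15-day default cohort).
#' @return data.frame with columns `time_index` (1-based), `day`
#'   (fractional), `fsr1_n` (right channel) and `fsr2_n` (left channel).
#' @export
cohort_force_trajectory <- function(config, epochs_per_day = 80) {
  stopifnot(inherits(config, "cohort_config"))
  n_pts <- config$n_days * epochs_per_day
  day_cont <- seq(1, config$n_days, length.out = n_pts)
  raw_per_epoch <- max(1, round(config$fs_force))   # 1 s epochs
  n_sub <- length(config$subjects)
  right <- matrix(0, n_pts, n_sub)
  left <- matrix(0, n_pts, n_sub)
  for (j in seq_len(n_sub)) {
    p <- config$subjects[[j]]
    s <- interpolate_fsi(p, day_cont, config$n_days)
    seed <- derive_seed(config$seed, paste0(p$subject_id, "/trajectory"))
    eps_sd <- config$noise_sd_force / sqrt(raw_per_epoch)
    noise <- with_seed(seed, matrix(rnorm(2 * n_pts, 0, eps_sd), ncol = 2))
    right[, j] <- p$base_force_n * (1 + s) / 2 + noise[, 1]
    left[, j] <- p$base_force_n * (1 - s) / 2 + noise[, 2]
  }
  data.frame(time_index = seq_len(n_pts), day = day_cont,
             fsr1_n = rowMeans(right), fsr2_n = rowMeans(left))
}
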