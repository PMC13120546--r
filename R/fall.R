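## Walker orientation classification and instability alerts.

#' Tilt angle of an acceleration vector
#'
#' Angle between the measured acceleration and the device z-axis (the
#' package's coordinate convention: z up, right-handed), i.e.
#' `acos(az / |a|)` in degrees.  Invariant to positive rescaling of the
#' vector; undefined at zero magnitude (free fall is handled by the
#' magnitude check in [classify_state()], not by tilt).
#'
#' @param ax,ay,az acceleration components in g-units; vectorized.
#' @return tilt in degrees, in \[0, 180\].
#' @export
tilt_angle <- function(ax, ay, az) {
  mag <- sqrt(ax^2 + ay^2 + az^2)
  if (any(!is.finite(mag)) || any(mag == 0)) {
    stop("tilt undefined for a zero-magnitude acceleration vector",
         call. = FALSE)
  }
  acos(pmin(1, pmax(-1, az / mag))) * 180 / pi
}

#' Orientation/instability thresholds
#'
#' @param incline_deg tilt below which the walker is upright (default 15).
#' @param fall_deg tilt at or above which the walker is falling (default
#'   60); between the two it is inclined.
#' @param freefall_floor_g acceleration magnitude below which the falling
#'   state is forced regardless of tilt (free-fall override, default 0.5).
#' @param debounce_ms a falling episode must persist this long before an
#'   alert is emitted (default 200).
#' @return an object of class `fall_thresholds`.
#' @export
fall_thresholds <- function(incline_deg = 15, fall_deg = 60,
                            freefall_floor_g = 0.5, debounce_ms = 200) {
  if (!(incline_deg > 0 && fall_deg > incline_deg)) {
    stop("need 0 < incline_deg < fall_deg", call. = FALSE)
  }
  if (freefall_floor_g < 0 || debounce_ms < 0) {
    stop("freefall floor and debounce must be non-negative", call. = FALSE)
  }
  structure(list(incline_deg = incline_deg, fall_deg = fall_deg,
                 freefall_floor_g = freefall_floor_g,
                 debounce_ms = debounce_ms),
            class = "fall_thresholds")
}

#' Classify walker orientation state
#'
#' Upright below the incline threshold, inclined between the thresholds,
#' falling at or above the fall threshold -- or whenever the acceleration
#' magnitude drops below the free-fall floor, whatever the tilt.
#'
#' @param tilt_deg tilt in \[0, 180\] degrees; vectorized.
#' @param magnitude_g acceleration magnitude in g-units.
#' @param thresholds a [fall_thresholds()].
#' @return character vector of `"upright"`, `"inclined"`, `"falling"`.
#' @export
classify_state <- function(tilt_deg, magnitude_g,
                           thresholds = fall_thresholds()) {
  stopifnot(inherits(thresholds, "fall_thresholds"))
  if (any(tilt_deg < 0 | tilt_deg > 180)) {
    stop("tilt must lie in [0, 180] degrees", call. = FALSE)
  }
  if (any(magnitude_g < 0)) stop("magnitude must be >= 0", call. = FALSE)
  state <- ifelse(tilt_deg < thresholds$incline_deg, "upright",
                  ifelse(tilt_deg < thresholds$fall_deg, "inclined", "falling"))
  state[magnitude_g < thresholds$freefall_floor_g] <- "falling"
  state
}

#' Detect instability alerts in an acceleration stream
#'
#' Isolates gravity by low-pass filtering each acceleration axis (2 Hz,
#' 2nd-order zero-phase Butterworth -- orientation cannot be read off raw
#' accelerometry through gait impact spikes and sensor jitter), computes
#' per-sample tilt and magnitude from the filtered vector, classifies every
#' sample, and emits one alert per contiguous falling episode that persists
#' at least the debounce time.
#'
#' @param stream data.frame with columns `timestamp_s`, `ax_g`, `ay_g`,
#'   `az_g`, time-ordered at an (approximately) constant rate.
#' @param thresholds a [fall_thresholds()].
#' @param smooth_gravity apply the gravity-isolation low-pass before
#'   classification (default TRUE; very short or irregular streams fall
#'   back to raw samples automatically).
#' @return list with `states` (per-sample data.frame: `timestamp_s`,
#'   `tilt_deg`, `magnitude_g`, `state`) and `alerts` (data.frame:
#'   `onset_s`, `state`, `tilt_deg` at episode onset).
#' @export
detect_events <- function(stream, thresholds = fall_thresholds(),
                          smooth_gravity = TRUE) {
  stopifnot(inherits(thresholds, "fall_thresholds"))
  stream <- as.data.frame(stream)
  stopifnot(all(c("timestamp_s", "ax_g", "ay_g", "az_g") %in% names(stream)))
  assert_time_ordered(stream$timestamp_s, "acceleration stream")
  n <- nrow(stream)
  if (n == 0) stop("empty acceleration stream", call. = FALSE)
  acc <- stream[c("ax_g", "ay_g", "az_g")]
  fs <- if (n > 1) 1 / stats::median(diff(stream$timestamp_s)) else NA_real_
  if (smooth_gravity && n > 12 && is.finite(fs) && fs > 4) {
    lp <- signal::butter(2, 2 / (fs / 2), type = "low")
    acc <- lapply(acc, function(v) signal::filtfilt(lp, v))
  }
  tilt <- tilt_angle(acc$ax_g, acc$ay_g, acc$az_g)
  mag <- sqrt(acc$ax_g^2 + acc$ay_g^2 + acc$az_g^2)
  state <- classify_state(tilt, pmax(mag, 0), thresholds)
  # contiguous falling episodes surviving the debounce window
  falling <- state == "falling"
  r <- rle(falling)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  alerts <- list()
  for (k in which(r$values)) {
    dur_ms <- (stream$timestamp_s[ends[k]] - stream$timestamp_s[starts[k]]) * 1000
    if (dur_ms >= thresholds$debounce_ms) {
      alerts[[length(alerts) + 1L]] <- data.frame(
        onset_s = stream$timestamp_s[starts[k]], state = "falling",
        tilt_deg = tilt[starts[k]], stringsAsFactors = FALSE)
    }
  }
  alerts <- if (length(alerts)) do.call(rbind, alerts) else {
    data.frame(onset_s = numeric(0), state = character(0),
               tilt_deg = numeric(0), stringsAsFactors = FALSE)
  }
  list(states = data.frame(timestamp_s = stream$timestamp_s, tilt_deg = tilt,
                           magnitude_g = mag, state = state,
                           stringsAsFactors = FALSE),
       alerts = alerts)
}
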