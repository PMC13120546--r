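## End-to-end orchestration: simulate -> analyse -> model -> report.
##
## File schemas (exact column names):
##   force     timestamp_s, adc_right, adc_left, f_right_n, f_left_n
##   accel     timestamp_s, ax_g, ay_g, az_g
##   emg       timestamp_s, emg_mv
##   intervals subject_id, group, interval_s

STREAM_SCHEMAS <- list(
  force = c("timestamp_s", "adc_right", "adc_left", "f_right_n", "f_left_n"),
  accel = c("timestamp_s", "ax_g", "ay_g", "az_g"),
  emg = c("timestamp_s", "emg_mv"),
  intervals = c("subject_id", "group", "interval_s"))

#' Assemble a full pipeline run configuration
#'
#' @param cohort a [cohort_config()] (default: the published-cohort
#'   calibration via [default_cohort()]).
#' @param haptic a [haptic_config()].
#' @param filter a [filter_spec()] for the sEMG band-pass.
#' @param fall a [fall_thresholds()].
#' @param gpr list of trajectory-model settings: `split_fraction`,
#'   `epochs_per_day`, `n_restarts`, `maxit`, `run_cv` (5-fold CV of the
#'   training split, off by default for speed).
#' @param stride list with `n_per_group` synthetic subjects per gait group.
#' @param master_seed overrides the cohort seed so one integer pins the
#'   whole run.
#' @param output_dir where stage artifacts are written (created if
#'   missing); `NULL` keeps everything in memory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = default_cohort(), haptic = haptic_config(),
                       filter = filter_spec(), fall = fall_thresholds(),
                       gpr = list(), stride = list(),
                       master_seed = NULL, output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(haptic, "haptic_config"),
            inherits(filter, "filter_spec"),
            inherits(fall, "fall_thresholds"))
  if (!is.null(master_seed)) cohort$seed <- as.integer(master_seed)
  gpr_defaults <- list(split_fraction = 0.8, epochs_per_day = 80,
                       n_restarts = 3, maxit = 60, run_cv = FALSE)
  gpr <- utils::modifyList(gpr_defaults, gpr)
  stride <- utils::modifyList(list(n_per_group = 5), stride)
  structure(list(cohort = cohort, haptic = haptic, filter = filter,
                 fall = fall, gpr = gpr, stride = stride,
                 output_dir = output_dir),
            class = "run_config")
}

## canonical JSON of the configuration -> provenance hash
config_hash <- function(config) {
  fnv1a_hex(jsonlite::toJSON(plainify(config), auto_unbox = TRUE, digits = NA,
                             null = "null"))
}

#' Validate a stream CSV against its schema
#'
#' Checks the expected columns, monotone non-decreasing timestamps and
#' value ranges (non-negative forces, ADC counts within \[0, 1023\],
#' positive stride intervals).
#'
#' @param path CSV file path.
#' @param modality one of `"force"`, `"accel"`, `"emg"`, `"intervals"`.
#' @return list with `ok` (logical), `errors`, `warnings` (character
#'   vectors naming offending columns/rows) and `n_rows`.
#' @export
validate_stream_file <- function(path,
                                 modality = c("force", "accel", "emg",
                                              "intervals")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- STREAM_SCHEMAS[[modality]]
  errors <- character(0)
  warnings <- character(0)
  missing <- setdiff(wanted, names(dat))
  if (length(missing)) {
    errors <- c(errors, sprintf("missing column(s): %s",
                                paste(missing, collapse = ", ")))
    return(list(ok = FALSE, errors = errors, warnings = warnings,
                n_rows = nrow(dat)))
  }
  if (modality != "intervals" && nrow(dat) > 1 &&
      is.unsorted(dat$timestamp_s, strictly = FALSE)) {
    errors <- c(errors, "timestamp_s is not monotone non-decreasing")
  }
  bad_row <- function(cond) if (any(cond)) which(cond)[1] else NA_integer_
  if (modality == "force") {
    for (col in c("adc_right", "adc_left")) {
      bad <- dat[[col]] < 0 | dat[[col]] > 1023
      if (any(bad)) {
        errors <- c(errors, sprintf("%s out of [0, 1023] at row %d",
                                    col, bad_row(bad)))
      }
    }
    for (col in c("f_right_n", "f_left_n")) {
      bad <- dat[[col]] < 0
      if (any(bad)) {
        errors <- c(errors, sprintf("%s negative at row %d", col, bad_row(bad)))
      }
    }
  }
  if (modality == "intervals") {
    bad <- dat$interval_s <= 0
    if (any(bad)) {
      errors <- c(errors, sprintf("interval_s non-positive at row %d",
                                  bad_row(bad)))
    }
  }
  if (nrow(dat) == 0) warnings <- c(warnings, "file has no data rows")
  list(ok = length(errors) == 0, errors = errors, warnings = warnings,
       n_rows = nrow(dat))
}

#' Render the cohort FSI report table
#'
#' Per-subject baseline/end-of-program FSI with percentage improvement,
#' FSI rounded half-up to 4 decimals and percentages to 2, plus the three
#' cohort means as a footer row.  Row order of the input does not affect
#' the footer.
#'
#' @param summary a [cohort_summary()].
#' @return data.frame with columns `subject_id`, `day1_fsi`, `day15_fsi`,
#'   `improvement_pct`; the last row (`subject_id == "Mean"`) is the
#'   footer.
#' @export
render_cohort_report <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  p <- summary$per_subject
  rbind(
    data.frame(subject_id = p$subject_id,
               day1_fsi = round_half_up(p$day1, 4),
               day15_fsi = round_half_up(p$day15, 4),
               improvement_pct = round_half_up(p$improvement_pct, 2),
               stringsAsFactors = FALSE),
    data.frame(subject_id = "Mean",
               day1_fsi = round_half_up(summary$mean_fsi_day1, 4),
               day15_fsi = round_half_up(summary$mean_fsi_day15, 4),
               improvement_pct = round_half_up(summary$mean_improvement_pct, 2),
               stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order -- synthetic cohort generation, per-day
#' session FSI and cohort summary, closed-loop feedback simulation,
#' instability detection on a programmed orientation sweep, the sEMG
#' endpoint statistics, trajectory GPR with chronological holdout, and the
#' stride-variance group comparison -- and consolidates the results.  With
#' an `output_dir` every stage also writes its CSV/JSON artifacts.  The
#' run is fully determined by the cohort master seed.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report` (a nested list; see the methods
#'   vignette for the layout).  Provenance carries the config hash and
#'   seed, never a wall-clock time, so identical configurations yield
#'   byte-identical serialised reports.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  out_dir <- config$output_dir
  writing <- !is.null(out_dir)
  if (writing && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  threshold <- default_asymmetry_threshold()
  subjects <- cohort$subjects
  days <- seq_len(cohort$n_days)

  ## simulate + symmetry + feedback, one pass over subject x day
  fsi_mat <- matrix(NA_real_, length(subjects), length(days))
  event_counts <- matrix(0L, length(subjects), length(days))
  diff_rows <- vector("list", 0L)
  for (si in seq_along(subjects)) {
    p <- subjects[[si]]
    for (d in days) {
      strm <- stage("synthetic_data", generate_force_pair(p, d, cohort))
      fsi_mat[si, d] <- stage("symmetry_analysis", session_fsi(strm))
      ev <- stage("feedback_loop",
                  run_feedback(strm, threshold, config$haptic))
      event_counts[si, d] <- nrow(ev)
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        day = d, diff = mean(strm$f_right_n) - mean(strm$f_left_n))
      if (writing && d %in% c(1L, cohort$n_days)) {
        utils::write.csv(as.data.frame(strm),
                         file.path(out_dir, sprintf("force_%s_day%02d.csv",
                                                    gsub("\\s+", "", p$subject_id), d)),
                         row.names = FALSE)
      }
    }
  }
  rows <- data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
                     day1 = fsi_mat[, 1], day15 = fsi_mat[, cohort$n_days])
  summary <- stage("symmetry_analysis", cohort_summary(rows))
  daily_diff <- do.call(rbind, diff_rows)
  interlimb <- stats::aggregate(diff ~ day, daily_diff, mean)

  ## fall detection on a programmed five-state orientation sweep
  sweep_states <- data.frame(
    state = c("upright", "inclined", "falling", "inclined", "falling"),
    duration_s = c(4, 3, 2, 3, 2))
  acc <- stage("synthetic_data",
               generate_accel_sequence(sweep_states, cohort,
                                       stream_id = "pipeline-sweep"))
  det <- stage("fall_detection", detect_events(acc$stream, config$fall))
  truth_falls <- sum(sweep_states$state == "falling")

  ## sEMG endpoint statistics
  amp <- function(day) {
    vapply(subjects, function(p) {
      rec <- stage("synthetic_data", generate_emg(p, day, cohort))
      rec <- stage("emg_pipeline", bandpass_filter(rec, config$filter))
      rec <- stage("emg_pipeline", wavelet_denoise(rec))
      mean_amplitude(rec)
    }, numeric(1))
  }
  amp1 <- amp(1L)
  amp15 <- amp(cohort$n_days)
  emg_test <- stage("emg_pipeline", paired_ttest(amp1, amp15))

  ## trajectory GPR
  traj <- stage("synthetic_data",
                cohort_force_trajectory(cohort, config$gpr$epochs_per_day))
  gpr_rep <- stage("gpr_model",
                   gp_trajectory_report(traj,
                                        split_fraction = config$gpr$split_fraction,
                                        n_restarts = config$gpr$n_restarts,
                                        seed = cohort$seed,
                                        maxit = config$gpr$maxit))
  gpr_out <- lapply(gpr_rep, function(ch) {
    hp <- ch$model$hyperparams
    list(r_squared = ch$holdout$r_squared, rmse = ch$holdout$rmse,
         split_fraction = ch$split_fraction,
         hyperparams = list(signal_variance = hp$signal_variance,
                            length_scale = hp$length_scale,
                            noise_variance = hp$noise_variance,
                            constant_mean = hp$constant_mean))
  })
  if (isTRUE(config$gpr$run_cv)) {
    n_train <- floor(config$gpr$split_fraction * nrow(traj))
    cv <- stage("gpr_model",
                gp_crossvalidate(traj$time_index[seq_len(n_train)],
                                 traj$fsr1_n[seq_len(n_train)],
                                 k_folds = 5, seed = cohort$seed,
                                 n_restarts = config$gpr$n_restarts,
                                 maxit = config$gpr$maxit))
    gpr_out$fsr1$cv_mean_r_squared <- cv$summary$mean_r_squared
  }

  ## stride-variance group comparison
  mk_group <- function(group) {
    lapply(seq_len(config$stride$n_per_group), function(i) {
      cfg <- stride_group_config(group,
                                 seed = derive_seed(cohort$seed,
                                                    sprintf("stride/%s/%d", group, i)))
      generate_stride_series(cfg, subject_id = sprintf("%s_%d", group, i))
    })
  }
  strides <- stage("stride_variability",
                   compare_groups(mk_group("control"), mk_group("als_like")))

  report <- structure(list(
    cohort_summary = list(
      mean_fsi_day1 = summary$mean_fsi_day1,
      mean_fsi_day15 = summary$mean_fsi_day15,
      mean_improvement_pct = summary$mean_improvement_pct,
      per_subject = summary$per_subject),
    fsi_trajectories = list(days = days, values = fsi_mat),
    interlimb_difference = interlimb,
    feedback = list(threshold = threshold,
                    events_per_day = colSums(event_counts)),
    fall_detection = list(alerts = nrow(det$alerts),
                          programmed_falls = truth_falls),
    emg = list(mean_day1_mv = emg_test$mean_day1_mv,
               mean_day15_mv = emg_test$mean_day15_mv,
               delta_mv = emg_test$delta_mv,
               t_statistic = emg_test$t_statistic, df = emg_test$df,
               p_value = emg_test$p_value),
    gpr = gpr_out,
    stride = list(var_control = strides$var_group_a,
                  var_als_like = strides$var_group_b,
                  ratio = strides$ratio, p_value = strides$p_value),
    provenance = list(config_hash = config_hash(config),
                      seed = cohort$seed,
                      package_version = as.character(utils::packageVersion("srwalker")))),
    class = "run_report")

  if (writing) {
    utils::write.csv(render_cohort_report(summary),
                     file.path(out_dir, "cohort_fsi_report.csv"),
                     row.names = FALSE)
    writeLines(serialise_report(report),
               file.path(out_dir, "run_report.json"))
  }
  report
}

#' Serialise a run report to canonical JSON
#'
#' Deterministic serialisation (no timestamps, full precision), so two
#' runs with the same master seed produce byte-identical payloads.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return a JSON character scalar.
#' @export
serialise_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  as.character(jsonlite::toJSON(plainify(report), auto_unbox = TRUE,
                                digits = NA, null = "null",
                                dataframe = "columns"))
}

#' @export
print.run_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat("== Rehabilitation walker run report ==\n")
  cat(sprintf("Cohort FSI: Day 1 %.4f -> Day %d %.4f  (mean improvement %.2f%%)\n",
              cs$mean_fsi_day1, max(x$fsi_trajectories$days),
              cs$mean_fsi_day15, cs$mean_improvement_pct))
  cat(sprintf("EMG: %.3f -> %.3f mV (delta %.3f), t(%d) = %.2f, p = %.2g\n",
              x$emg$mean_day1_mv, x$emg$mean_day15_mv, x$emg$delta_mv,
              x$emg$df, x$emg$t_statistic, x$emg$p_value))
  cat(sprintf("GPR holdout: FSR1 R^2 = %.4f (RMSE %.4f), FSR2 R^2 = %.4f (RMSE %.4f)\n",
              x$gpr$fsr1$r_squared, x$gpr$fsr1$rmse,
              x$gpr$fsr2$r_squared, x$gpr$fsr2$rmse))
  cat(sprintf("Fall alerts: %d (programmed falling episodes: %d)\n",
              x$fall_detection$alerts, x$fall_detection$programmed_falls))
  cat(sprintf("Stride variance: control %.5f vs ALS-like %.5f s^2 (ratio %.2f, p = %.2g)\n",
              x$stride$var_control, x$stride$var_als_like, x$stride$ratio,
              x$stride$p_value))
  cat(sprintf("Provenance: seed %d, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}

#' Write a stream data.frame as a schema CSV with a JSON sidecar
#'
#' @param stream data.frame following one of the package stream schemas.
#' @param path output CSV path; the sidecar is written as `<path>.json`.
#' @param modality schema name.
#' @param meta named list echoed into the sidecar (seed, config, ...).
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(stream, path,
                             modality = c("force", "accel", "emg",
                                          "intervals"),
                             meta = list()) {
  modality <- match.arg(modality)
  stream <- as.data.frame(stream)
  wanted <- STREAM_SCHEMAS[[modality]]
  stopifnot(all(wanted %in% names(stream)))
  utils::write.csv(stream[wanted], path, row.names = FALSE)
  sidecar <- c(list(modality = modality, n_rows = nrow(stream)), meta)
  writeLines(as.character(jsonlite::toJSON(sidecar, auto_unbox = TRUE,
                                           digits = NA)),
             paste0(path, ".json"))
  invisible(path)
}
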