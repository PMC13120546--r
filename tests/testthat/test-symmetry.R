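# Force Symmetry Index, trajectories, cohort summaries, calibration.

test_that("compute_fsi matches analytic cases and rejects degenerate input", {
  expect_equal(compute_fsi(10, 10), 0)
  expect_equal(compute_fsi(10, 0), 1)
  expect_equal(compute_fsi(300, 100), 0.5)
  expect_error(compute_fsi(0, 0), "undefined")
  expect_error(compute_fsi(-1, 5), "non-negative")
})

test_that("FSI is symmetric, scale-invariant and bounded on random force pairs", {
  set.seed(101)
  for (i in 1:200) {
    a <- runif(1, 0, 500); b <- runif(1, 0, 500); k <- runif(1, 0.01, 50)
    if (a + b == 0) next
    f <- compute_fsi(a, b)
    expect_equal(f, compute_fsi(b, a))
    expect_equal(f, compute_fsi(k * a, k * b))
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("session_fsi aggregates session-mean forces with a non-contact floor", {
  strm <- data.frame(timestamp_s = 0:9 / 10,
                     f_right_n = rep(300, 10), f_left_n = rep(100, 10))
  expect_equal(session_fsi(strm), 0.5)
  # permuted channels with equal means give zero
  strm2 <- data.frame(timestamp_s = 0:3 / 10,
                      f_right_n = c(10, 20, 30, 40),
                      f_left_n = c(40, 30, 20, 10))
  expect_equal(session_fsi(strm2), 0)
  # non-contact samples (both channels ~0) are excluded, not averaged in
  strm3 <- rbind(strm, data.frame(timestamp_s = 1 + 0:9 / 10,
                                  f_right_n = 0.1, f_left_n = 0.1))
  expect_equal(session_fsi(strm3), 0.5)
  expect_error(session_fsi(strm3[11:20, ]), "undefined")
})

test_that("improvement percentages reproduce every published subject row to 2 decimals", {
  ref <- pilot_cohort_fsi()
  imp <- improvement_percent(ref$day1, ref$day15)
  expect_equal(srwalker:::round_half_up(imp, 2), ref$improvement_pct)
  expect_equal(improvement_percent(0.5, 0.5), 0)
  expect_error(improvement_percent(0, 0.1), "undefined")
})

test_that("cohort_summary reproduces the published cohort means to 4 decimals", {
  ref <- pilot_cohort_fsi()
  cs <- cohort_summary(ref[, c("subject_id", "day1", "day15")])
  expect_equal(srwalker:::round_half_up(cs$mean_fsi_day1, 4), 0.9691)
  expect_equal(srwalker:::round_half_up(cs$mean_fsi_day15, 4), 0.2019)
  expect_equal(srwalker:::round_half_up(cs$mean_improvement_pct, 2), 79.26)
  one <- cohort_summary(data.frame(day1 = 0.5, day15 = 0.25))
  expect_equal(one$mean_fsi_day1, 0.5)
  expect_equal(one$mean_improvement_pct, 50)
  expect_error(cohort_summary(data.frame(day1 = numeric(0),
                                         day15 = numeric(0))), "at least one")
})

test_that("zero-noise synthetic cohort reproduces every published FSI to 4 decimals", {
  cfg <- default_cohort(seed = 1, noise_sd_force = 0, session_length_s = 4)
  ref <- pilot_cohort_fsi()
  for (i in seq_along(cfg$subjects)) {
    p <- cfg$subjects[[i]]
    expect_equal(round(session_fsi(generate_force_pair(p, 1, cfg)), 4),
                 ref$day1[i])
    expect_equal(round(session_fsi(generate_force_pair(p, 15, cfg)), 4),
                 ref$day15[i])
  }
})

test_that("interlimb difference preserves sign and decays on calibrated cohorts", {
  daily <- data.frame(day = rep(1:2, each = 3),
                      f_right_n = c(5, 5, 5, 7, 7, 7),
                      f_left_n = c(5, 5, 5, 4, 4, 4))
  out <- interlimb_voltage_difference(daily)
  expect_equal(out$mean_diff, c(0, 3))
  # Table-calibrated zero-noise cohort: |right - left| non-increasing in day
  cfg <- default_cohort(seed = 1, noise_sd_force = 0, session_length_s = 4)
  p <- cfg$subjects[[1]]
  all_days <- do.call(rbind, lapply(1:15, function(d) {
    s <- generate_force_pair(p, d, cfg)
    data.frame(day = d, f_right_n = s$f_right_n, f_left_n = s$f_left_n)
  }))
  traj <- interlimb_voltage_difference(all_days)
  expect_true(all(diff(abs(traj$mean_diff)) <= 1e-9))
})

test_that("ADC-to-force interpolation matches a hand-computed oracle and clamps", {
  curve <- calibration_curve(c(0, 20, 60), c(0, 300, 900))
  expect_equal(adc_to_force(300, curve), 20)           # exact knot
  expect_equal(adc_to_force(150, curve), 10)           # midpoint mean
  expect_equal(adc_to_force(600, curve), 40)           # hand oracle between 2-3
  expect_equal(adc_to_force(1000, curve), 60)          # clamped extrapolation
  expect_error(adc_to_force(-1, curve), "0, 1023")
  expect_error(calibration_curve(c(10, 5), c(0, 100)), "increasing")
  expect_error(calibration_curve(1, 2), ">= 2")
})
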