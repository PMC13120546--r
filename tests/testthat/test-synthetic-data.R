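# Seeded multimodal generator: calibration targets, determinism, ranges.

test_that("zero-noise force streams hit the interpolated FSI target exactly", {
  cfg <- tiny_cohort(noise_sd_force = 0)
  p <- cfg$subjects[[1]]   # published Subject 1 endpoints
  expect_equal(session_fsi(generate_force_pair(p, 1, cfg)), 0.9526,
               tolerance = 1e-12)
  expect_equal(session_fsi(generate_force_pair(p, cfg$n_days, cfg)), 0.1530,
               tolerance = 1e-12)
  # a symmetric profile yields identical left/right series up to noise
  sym <- subject_profile("sym", 0, 0)
  cfg2 <- cohort_config(list(sym), n_days = 3, session_length_s = 5,
                        noise_sd_force = 0, seed = 1)
  strm <- generate_force_pair(sym, 2, cfg2)
  expect_equal(strm$f_right_n, strm$f_left_n, tolerance = 1e-12)
})

test_that("force generation is deterministic in the master seed and rejects bad days", {
  cfg <- tiny_cohort(seed = 42)
  a <- generate_force_pair(cfg$subjects[[2]], 2, cfg)
  b <- generate_force_pair(cfg$subjects[[2]], 2, cfg)
  expect_identical(a, b)
  cfg_other <- tiny_cohort(seed = 43)
  c <- generate_force_pair(cfg_other$subjects[[2]], 2, cfg_other)
  expect_false(identical(a$f_right_n, c$f_right_n))
  expect_error(generate_force_pair(cfg$subjects[[1]], 0, cfg), "day must")
  expect_error(generate_force_pair(cfg$subjects[[1]], 99, cfg), "day must")
})

test_that("forces are non-negative and ADC counts stay within the 10-bit range", {
  cfg <- tiny_cohort(noise_sd_force = 8)   # exaggerated noise
  for (d in seq_len(cfg$n_days)) {
    s <- generate_force_pair(cfg$subjects[[1]], d, cfg)
    expect_true(all(s$f_right_n >= 0) && all(s$f_left_n >= 0))
    expect_true(all(s$adc_right >= 0 & s$adc_right <= 1023))
    expect_true(all(s$adc_left >= 0 & s$adc_left <= 1023))
  }
})

test_that("noisy default cohort reproduces the published Day-1 mean FSI within 0.02", {
  cfg <- default_cohort(seed = 11)
  day1 <- vapply(cfg$subjects,
                 function(p) session_fsi(generate_force_pair(p, 1, cfg)),
                 numeric(1))
  expect_lt(abs(mean(day1) - 0.9691), 0.02)
})

test_that("clean EMG hits the interpolated amplitude target and endpoints match calibration", {
  cfg <- default_cohort(seed = 3)
  p <- cfg$subjects[[4]]
  rec <- generate_emg(p, 1, cfg, drift_amplitude_mv = 0, hf_amplitude_mv = 0,
                      duration_s = 4)
  clean <- attr(rec, "clean_mv")
  target <- attr(rec, "target_amplitude_mv")
  expect_equal(mean(abs(clean)), target, tolerance = 0.02)
  expect_equal(target, p$emg_day1_mv)
  rec15 <- generate_emg(p, 15, cfg, duration_s = 4)
  expect_equal(attr(rec15, "target_amplitude_mv"), p$emg_day15_mv)
  # cohort endpoint means equal the published values by construction
  t1 <- vapply(cfg$subjects, `[[`, numeric(1), "emg_day1_mv")
  t15 <- vapply(cfg$subjects, `[[`, numeric(1), "emg_day15_mv")
  expect_equal(mean(t1), 0.885, tolerance = 1e-12)
  expect_equal(mean(t15), 5.138, tolerance = 1e-12)
})

test_that("accelerometer sequences follow programmed tilt with exact ground truth", {
  cfg <- tiny_cohort()
  up <- generate_accel_sequence(
    data.frame(state = "upright", duration_s = 2), cfg, noise_sd_g = 0)
  expect_equal(tilt_angle(up$stream$ax_g, up$stream$ay_g, up$stream$az_g),
               rep(0, nrow(up$stream)), tolerance = 1e-9)
  two <- generate_accel_sequence(
    data.frame(state = c("upright", "falling"), duration_s = c(1.5, 1)),
    cfg, noise_sd_g = 0)
  expect_equal(two$transitions$time_s, c(0, 1.5))
  expect_equal(two$transitions$state, c("upright", "falling"))
  expect_error(generate_accel_sequence(
    data.frame(state = character(0), duration_s = numeric(0)), cfg),
    "non-empty")
  expect_error(generate_accel_sequence(
    data.frame(state = "upright", duration_s = -1), cfg), "positive")
})

test_that("stride series follow the timing-jitter model", {
  cfg0 <- stride_group_config("control", jitter_sd_s = 0, n_strides = 20)
  s0 <- generate_stride_series(cfg0)
  expect_equal(s0$intervals_s, rep(1.1, 19), tolerance = 1e-12)
  expect_equal(stride_time_variance(s0), 0, tolerance = 1e-24)
  # large-n interval variance matches the analytic 2 sigma^2
  cfgj <- stride_group_config("control", jitter_sd_s = 0.05,
                              n_strides = 10001, seed = 5)
  v <- stride_time_variance(generate_stride_series(cfgj))
  expect_lt(abs(v - 2 * 0.05^2) / (2 * 0.05^2), 0.05)
  expect_error(stride_group_config("control", jitter_sd_s = -0.1), ">= 0")
})

test_that("ALS-like stride variance exceeds control in nearly all seeded replicates", {
  wins <- vapply(1:200, function(r) {
    va <- stride_time_variance(
      generate_stride_series(stride_group_config("als_like", seed = r)))
    vc <- stride_time_variance(
      generate_stride_series(stride_group_config("control", seed = r + 1000)))
    va > vc
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("the cohort trajectory is smooth, decaying and seeded", {
  cfg <- tiny_cohort(n_days = 5, seed = 2)
  tr <- cohort_force_trajectory(cfg, epochs_per_day = 40)
  expect_equal(nrow(tr), 200)
  expect_identical(tr, cohort_force_trajectory(cfg, epochs_per_day = 40))
  # right channel decays, left rises as load symmetrises
  expect_gt(mean(tr$fsr1_n[1:20]), mean(tr$fsr1_n[181:200]))
  expect_lt(mean(tr$fsr2_n[1:20]), mean(tr$fsr2_n[181:200]))
})
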