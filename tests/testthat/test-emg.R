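# sEMG conditioning chain and longitudinal statistics.

test_that("the band-pass passes 150 Hz, blocks 1 Hz and kills DC", {
  fs <- 4000
  t <- (0:(8 * fs - 1)) / fs
  core <- (fs + 1):(7 * fs)   # interior window, away from filter edges
  pass <- emg_record(sin(2 * pi * 150 * t), fs)
  out <- bandpass_filter(pass)
  gain_pass <- max(abs(out$samples_mv[core]))
  expect_lt(abs(gain_pass - 1), 0.01)
  stopb <- emg_record(sin(2 * pi * 1 * t), fs)
  gain_stop <- max(abs(bandpass_filter(stopb)$samples_mv[core]))
  expect_lt(gain_stop, 0.01)
  dc <- emg_record(rep(2, 4 * fs), fs)
  expect_lt(max(abs(bandpass_filter(dc)$samples_mv[core[1:fs]])), 1e-6)
  # band edge above Nyquist is rejected with a corrective message
  expect_error(bandpass_filter(emg_record(rnorm(4000), 1800),
                               filter_spec(30, 900)), "Nyquist")
})

test_that("records advance raw -> filtered -> denoised and stages are enforced", {
  rec <- emg_record(rnorm(4096), 4000)
  expect_equal(rec$stage, "raw")
  f <- bandpass_filter(rec)
  expect_equal(f$stage, "filtered")
  expect_equal(length(f$samples_mv), 4096)
  d <- wavelet_denoise(f)
  expect_equal(d$stage, "denoised")
  expect_equal(length(d$samples_mv), 4096)
  expect_error(bandpass_filter(f), "raw record")
  expect_error(wavelet_denoise(rec), "filtered record")
  expect_error(wavelet_denoise(emg_record(rnorm(32), 4000,
                                          stage = "filtered")), "too short")
})

test_that("the db4 transform matches frozen reference coefficients and inverts exactly", {
  x <- sin((0:15) * 0.7) + 0.1 * (0:15)
  s <- srwalker:::dwt_step(x)
  # reference values computed with an independent wavelet implementation
  expect_equal(s$cA,
               c(1.430978360797, 0.392135708279, 1.684784066235,
                 0.965739385261, -0.416155001106, 0.302673888077,
                 2.405039452033, 2.838217768374), tolerance = 1e-10)
  expect_equal(s$cD,
               c(-0.138524663215, -0.088909285087, 0.052849002987,
                 0.092414086065, -0.021434286643, -0.099700334987,
                 0.130566401687, 0.395090748719), tolerance = 1e-10)
  expect_equal(srwalker:::idwt_step(s$cA, s$cD), x, tolerance = 1e-12)
  set.seed(4)
  y <- rnorm(256)
  expect_equal(srwalker:::idwt_db4(srwalker:::dwt_db4(y, 4)), y,
               tolerance = 1e-12)
})

test_that("wavelet denoising is near-identity on clean signals and raises SNR on noisy ones", {
  fs <- 4000
  t <- (0:(16 * 1024 - 1)) / fs
  burst <- sin(2 * pi * 4 * t)^2 * sin(2 * pi * 100 * t)
  clean_rec <- emg_record(burst, fs, stage = "filtered")
  den <- wavelet_denoise(clean_rec)
  expect_lt(sqrt(mean((den$samples_mv - burst)^2)) / sqrt(mean(burst^2)), 0.05)
  # zero in, zero out
  z <- wavelet_denoise(emg_record(rep(0, 1024), fs, stage = "filtered"))
  expect_equal(z$samples_mv, rep(0, 1024))
  # additive white noise at known SNR: denoising strictly improves it
  set.seed(8)
  for (sd in c(0.1, 0.3, 0.6)) {
    noisy <- burst + rnorm(length(burst), 0, sd)
    dn <- wavelet_denoise(emg_record(noisy, fs, stage = "filtered"))
    expect_gt(snr_db(burst, dn$samples_mv), snr_db(burst, noisy))
  }
})

test_that("amplitude metrics rectify correctly and passband signals survive the chain", {
  fs <- 4000
  const <- emg_record(rep(2, 2048), fs, stage = "denoised")
  expect_equal(mean_amplitude(const), 2)
  sq <- emg_record(rep(c(3, -3), 1024), fs, stage = "denoised")
  expect_equal(mean_amplitude(sq), 3)
  expect_equal(rms_amplitude(sq), 3)
  # passband fidelity: filtering + denoising changes the mean rectified
  # amplitude of an in-band tone by under 2%
  t <- (0:(8 * fs - 1)) / fs
  tone <- emg_record(sin(2 * pi * 120 * t), fs)
  out <- wavelet_denoise(bandpass_filter(tone))
  core <- (fs + 1):(7 * fs)
  expect_lt(abs(mean(abs(out$samples_mv[core])) / mean(abs(tone$samples_mv[core])) - 1),
            0.02)
})

test_that("the paired t-test matches its closed form and an independent oracle", {
  # hand oracle: d = (1,2,3,4), t = 2.5 / (1.29099/2)
  r <- paired_ttest(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(r$t_statistic, 3.872983, tolerance = 1e-6)
  expect_equal(r$df, 3L)
  set.seed(66)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    a <- rnorm(n); b <- rnorm(n, 0.5)
    mine <- paired_ttest(a, b)
    ref <- t.test(b, a, paired = TRUE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  expect_equal(paired_ttest(rnorm(10), rnorm(10))$df, 9L)
  expect_error(paired_ttest(1:4, (1:4) + 2), "degenerate")
  expect_error(paired_ttest(1:4, 1:5), "equal length")
})

test_that("Q-Q pairs use (i - 1/2)/n plotting positions", {
  q <- normality_qq(c(5, 1, 3))
  expect_equal(nrow(q), 3)
  expect_equal(q$empirical, c(1, 3, 5))
  expect_equal(q$theoretical, qnorm(c(0.5, 1.5, 2.5) / 3))
  set.seed(2)
  big <- normality_qq(rnorm(10000))
  interior <- 500:9500   # extreme order statistics converge more slowly
  expect_lt(max(abs(big$empirical - big$theoretical)[interior]), 0.05)
  const <- normality_qq(rep(1, 5))
  expect_true(all(const$empirical == 1))
  expect_error(normality_qq(1:2), "n >= 3")
})
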