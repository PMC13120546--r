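# Gaussian process regression: kernel algebra, likelihood, prediction,
# evaluation, cross-validation.  Dense-inverse oracles are coded inline and
# independently of the package's Cholesky path.

oracle_predict <- function(hp, x, y, xs) {
  K <- hp$signal_variance * exp(-outer(x, x, "-")^2 / (2 * hp$length_scale^2)) +
    diag(hp$noise_variance, length(x))
  ks <- hp$signal_variance * exp(-outer(x, xs, "-")^2 / (2 * hp$length_scale^2))
  Kinv <- solve(K)
  yc <- y - hp$constant_mean
  list(mean = hp$constant_mean + drop(t(ks) %*% Kinv %*% yc),
       var = hp$signal_variance - diag(t(ks) %*% Kinv %*% ks))
}

oracle_lml <- function(hp, x, y) {
  K <- hp$signal_variance * exp(-outer(x, x, "-")^2 / (2 * hp$length_scale^2)) +
    diag(hp$noise_variance, length(x))
  yc <- y - hp$constant_mean
  as.numeric(-0.5 * t(yc) %*% solve(K) %*% yc -
               0.5 * determinant(K)$modulus - length(x) / 2 * log(2 * pi))
}

test_that("the RBF kernel matches its closed form", {
  hp <- gp_hyperparams(2, 1)
  expect_equal(rbf_kernel(3, 3, hp), 2)
  expect_equal(rbf_kernel(0, 1, hp), 2 * exp(-0.5), tolerance = 1e-12)
  expect_lt(rbf_kernel(0, 100, hp), 1e-3 * 2)
  K <- rbf_kernel(1:5, 1:5, hp)
  expect_equal(K, t(K))
  set.seed(1)
  for (i in 1:20) {                       # PSD on random inputs
    x <- runif(8, -5, 5)
    hpr <- gp_hyperparams(runif(1, 0.1, 5), runif(1, 0.1, 5))
    ev <- eigen(rbf_kernel(x, x, hpr), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-8)
  }
})

test_that("log marginal likelihood matches the dense oracle to 10 significant digits", {
  hp1 <- gp_hyperparams(0.6, 2, 0.4, 0)
  expect_equal(gp_log_marginal_likelihood(hp1, 0, 0), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  set.seed(17)
  for (n in c(3, 8, 20)) {
    x <- sort(runif(n, 0, 10))
    y <- sin(x) + rnorm(n, 0, 0.2)
    hp <- gp_hyperparams(runif(1, 0.5, 3), runif(1, 0.5, 3),
                         runif(1, 0.05, 0.5), mean(y))
    mine <- gp_log_marginal_likelihood(hp, x, y)
    expect_equal(mine, oracle_lml(hp, x, y), tolerance = 1e-10)
  }
})

test_that("predictions match the dense oracle and respect GP limit behaviour", {
  set.seed(23)
  x <- sort(runif(4, 0, 8))
  y <- cos(x)
  hp <- gp_hyperparams(1.5, 1.2, 0.3, mean(y))
  m <- gp_model_fixed(x, y, hp)
  xs <- c(0.5, 3.3, 7.9)
  pred <- gp_predict(m, xs)
  orc <- oracle_predict(hp, x, y, xs)
  expect_equal(pred$mean, orc$mean, tolerance = 1e-10)
  expect_equal(pred$variance, orc$var, tolerance = 1e-10)
  # noiseless interpolation
  hp0 <- gp_hyperparams(1.5, 1.2, 0, mean(y))
  m0 <- gp_model_fixed(x, y, hp0)
  expect_equal(gp_predict(m0, x)$mean, y, tolerance = 1e-8)
  # prior reversion far from the data
  far <- gp_predict(m, 1e4)
  expect_equal(far$mean, hp$constant_mean, tolerance = 1e-8)
  expect_equal(far$variance, hp$signal_variance, tolerance = 1e-8)
  # latent variance bounded by the signal variance, observation band wider
  expect_true(all(pred$variance >= 0 & pred$variance <= hp$signal_variance + 1e-12))
  expect_true(all(pred$ci95_high - pred$ci95_low >=
                    2 * 1.96 * sqrt(hp$noise_variance) - 1e-12))
})

test_that("adding a training point never increases latent predictive variance", {
  set.seed(31)
  x <- sort(runif(10, 0, 10)); y <- sin(x)
  hp <- gp_hyperparams(1, 2, 0.1, 0)
  xs <- seq(0, 10, by = 0.5)
  v1 <- gp_predict(gp_model_fixed(x, y, hp), xs)$variance
  v2 <- gp_predict(gp_model_fixed(c(x, 5.25), c(y, sin(5.25)), hp), xs)$variance
  expect_true(all(v2 <= v1 + 1e-9))
})

test_that("hyperparameter optimisation recovers known generating parameters", {
  truth <- c(sf2 = 1, l = 3, sn2 = 0.01)
  x <- seq(0, 60, length.out = 200)
  est <- sapply(1:20, function(r) {
    y <- simulate_gp(x, truth["sf2"], truth["l"], truth["sn2"], seed = 400 + r)
    hp <- gp_fit(x, y, n_restarts = 4, seed = r, maxit = 80)$hyperparams
    c(hp$signal_variance, hp$length_scale, hp$noise_variance)
  })
  med <- apply(est, 1, median)
  for (k in 1:3) {
    expect_lt(abs(log(med[k] / truth[k])), log(1.3))
  }
})

test_that("degenerate and near-constant outputs are handled gracefully", {
  m <- gp_fit(1:10, rep(2, 10), n_restarts = 2, seed = 1)
  p <- gp_predict(m, c(2.5, 20))
  expect_equal(p$mean, c(2, 2), tolerance = 1e-6)
  expect_lt(m$hyperparams$signal_variance, 1e-6)
})

test_that("holdout metrics follow the sum-of-squares decomposition", {
  set.seed(5)
  x <- 1:30; y <- 0.1 * x + rnorm(30, 0, 0.1)
  m <- gp_fit(x[1:20], y[1:20], n_restarts = 2, seed = 2)
  ev <- gp_evaluate(m, x[21:30], y[21:30])
  pred <- gp_predict(m, x[21:30])$mean
  expect_equal(ev$rmse, sqrt(mean((y[21:30] - pred)^2)), tolerance = 1e-12)
  expect_equal(ev$r_squared,
               1 - sum((y[21:30] - pred)^2) / sum((y[21:30] - mean(y[21:30]))^2),
               tolerance = 1e-12)
  expect_error(gp_evaluate(m, numeric(0), numeric(0)), "empty")
  expect_error(gp_evaluate(m, 1:3, rep(1, 3)), "zero-variance")
})

test_that("cross-validation partitions into contiguous blocks and is internally consistent", {
  # a smooth longitudinal trend + noise, the regime the model is built for:
  # fold scores and the chronological holdout should tell the same story
  tr <- cohort_force_trajectory(tiny_cohort(seed = 4, n_days = 5),
                                epochs_per_day = 40)
  x <- tr$time_index; y <- tr$fsr1_n
  cv <- gp_crossvalidate(x[1:160], y[1:160], k_folds = 5, seed = 3,
                         n_restarts = 2, maxit = 40)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sum(cv$folds$n_test), 160)
  holdout <- gp_evaluate(gp_fit(x[1:160], y[1:160], n_restarts = 2, seed = 3,
                                maxit = 40),
                         x[161:200], y[161:200])
  expect_lt(abs(cv$summary$mean_r_squared - holdout$r_squared), 0.1)
  expect_error(gp_crossvalidate(1:3, 1:3, k_folds = 5), "k_folds")
})
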