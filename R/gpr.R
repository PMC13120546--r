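## Gaussian Process Regression with an RBF kernel, constant mean and
## Gaussian observation noise, written from first principles: exact dense
## inference via Cholesky factorisation and type-II maximum likelihood
## (multi-start gradient ascent of the log marginal likelihood in
## log-hyperparameter space).

#' Gaussian process hyperparameters
#'
#' @param signal_variance RBF signal variance (sigma_f^2 > 0), squared
#'   output units.
#' @param length_scale characteristic length-scale (l > 0), input units.
#' @param noise_variance observation noise variance (sigma_n^2 >= 0).
#' @param constant_mean constant prior mean, output units.
#' @return an object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(signal_variance, length_scale,
                           noise_variance = 0, constant_mean = 0) {
  if (!(signal_variance > 0)) stop("signal_variance must be > 0", call. = FALSE)
  if (!(length_scale > 0)) stop("length_scale must be > 0", call. = FALSE)
  if (noise_variance < 0) stop("noise_variance must be >= 0", call. = FALSE)
  structure(list(signal_variance = signal_variance,
                 length_scale = length_scale,
                 noise_variance = noise_variance,
                 constant_mean = constant_mean),
            class = "gp_hyperparams")
}

#' Radial basis function (squared-exponential) kernel
#'
#' `k(x, x') = sigma_f^2 * exp(-(x - x')^2 / (2 l^2))` evaluated for all
#' pairs of the two input vectors.
#'
#' @param x,x_prime numeric input vectors.
#' @param hp a [gp_hyperparams()].
#' @return the `length(x)` by `length(x_prime)` covariance matrix (dropped
#'   to a scalar when both inputs are scalars).
#' @export
rbf_kernel <- function(x, x_prime, hp) {
  stopifnot(inherits(hp, "gp_hyperparams"))
  d <- outer(x, x_prime, "-")
  k <- hp$signal_variance * exp(-(d^2) / (2 * hp$length_scale^2))
  if (length(x) == 1L && length(x_prime) == 1L) drop(k) else k
}

## Cholesky of K + sigma_n^2 I with escalating jitter (1e-10 -> 1e-6,
## scaled by the signal variance).  Errors naming the hyperparameters if
## the matrix stays indefinite.
chol_with_jitter <- function(K, hp) {
  n <- nrow(K)
  for (j in c(0, 10^seq(-10, -6))) {
    Kj <- K + diag(hp$noise_variance + j * hp$signal_variance, n)
    L <- tryCatch(t(chol(Kj)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop(sprintf(paste0("kernel matrix not positive definite after maximum ",
                      "jitter (signal_variance=%g, length_scale=%g, ",
                      "noise_variance=%g)"),
               hp$signal_variance, hp$length_scale, hp$noise_variance),
       call. = FALSE)
}

#' Log marginal likelihood of a GP with fixed hyperparameters
#'
#' `-1/2 yc' (K + sigma_n^2 I)^-1 yc - 1/2 log|K + sigma_n^2 I|
#'  - n/2 log(2 pi)` with `yc = y - constant_mean`.
#'
#' @param hp a [gp_hyperparams()].
#' @param x,y training inputs and outputs (equal length, n >= 1).
#' @return the log marginal likelihood (scalar).
#' @export
gp_log_marginal_likelihood <- function(hp, x, y) {
  stopifnot(inherits(hp, "gp_hyperparams"), length(x) == length(y),
            length(x) >= 1)
  yc <- y - hp$constant_mean
  K <- rbf_kernel(x, x, hp)
  if (length(x) == 1L) K <- matrix(K, 1, 1)
  f <- chol_with_jitter(K, hp)
  L <- f$L
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  -0.5 * sum(yc * alpha) - sum(log(diag(L))) - length(x) / 2 * log(2 * pi)
}

## negative LML and its gradient in theta = (log sf2, log l, log sn2);
## D2 is the precomputed squared-distance matrix, yc the centered outputs.
neg_lml_with_grad <- function(theta, D2, yc) {
  n <- length(yc)
  sf2 <- exp(theta[1]); l <- exp(theta[2]); sn2 <- exp(theta[3])
  Krbf <- sf2 * exp(-D2 / (2 * l^2))
  K <- Krbf + diag(sn2 + 1e-10 * sf2, n)
  L <- tryCatch(t(chol(K)), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, gradient = c(0, 0, 0)))
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  lml <- -0.5 * sum(yc * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  Kinv <- chol2inv(t(L))
  A <- tcrossprod(alpha) - Kinv          # alpha alpha' - K^-1
  g_sf2 <- 0.5 * sum(A * Krbf)           # dK/dlog sf2 = Krbf
  g_l <- 0.5 * sum(A * (Krbf * D2 / l^2))
  g_sn2 <- 0.5 * sum(diag(A)) * sn2
  list(value = -lml, gradient = -c(g_sf2, g_l, g_sn2))
}

#' Fit a Gaussian process by maximum marginal likelihood
#'
#' The constant mean is fixed at the training-output average; the three
#' kernel hyperparameters are optimised in log space with L-BFGS-B and
#' analytic gradients, restarted from `n_restarts` seeded log-uniform draws
#' (plus one data-driven heuristic start).  The best restart by final log
#' marginal likelihood wins.
#'
#' @param x,y training inputs/outputs, n >= 3.
#' @param n_restarts number of random restarts (default 8).
#' @param seed seed for the restart draws.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return an object of class `gp_model` holding the optimised
#'   [gp_hyperparams()], the training data and the cached Cholesky
#'   factorisation.
#' @export
gp_fit <- function(x, y, n_restarts = 8, seed = 1, maxit = 100) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("gp_fit needs n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  mu0 <- mean(y)
  yc <- y - mu0
  D2 <- outer(x, x, "-")^2
  var_y <- max(stats::var(y), 1e-12)
  r <- max(diff(range(x)), 1e-8)
  lb <- log(c(1e-6 * var_y, r / 1e3, 1e-9 * var_y))
  ub <- log(c(1e3 * var_y, 1e2 * r, 1e1 * var_y))
  starts <- list(log(c(var_y, r / 8, 0.1 * var_y)))
  if (n_restarts > 1) {
    draws <- with_seed(derive_seed(seed, "gp/restarts"), {
      matrix(stats::runif(3 * (n_restarts - 1)), ncol = 3)
    })
    for (i in seq_len(n_restarts - 1)) {
      starts[[i + 1]] <- lb + draws[i, ] * (ub - lb)
    }
  }
  # optim asks for value and gradient at the same point separately;
  # cache the last evaluation so each point costs one factorisation
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- neg_lml_with_grad(th, D2, yc)
      cache$key <- key
    }
    cache$res
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, fn = function(th) eval_cached(th)$value,
                   gr = function(th) eval_cached(th)$gradient,
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < 1e10 &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("all optimisation restarts failed (non-PD kernel at every start)",
         call. = FALSE)
  }
  th <- best$par
  hp <- gp_hyperparams(signal_variance = exp(th[1]),
                       length_scale = exp(th[2]),
                       noise_variance = exp(th[3]),
                       constant_mean = mu0)
  new_gp_model(x, y, hp, lml = -best$value)
}

## assemble a gp_model (also the entry point for fixed hyperparameters)
new_gp_model <- function(x, y, hp, lml = NULL) {
  K <- rbf_kernel(x, x, hp)
  if (length(x) == 1L) K <- matrix(K, 1, 1)
  f <- chol_with_jitter(K, hp)
  yc <- y - hp$constant_mean
  alpha <- backsolve(t(f$L), forwardsolve(f$L, yc))
  if (is.null(lml)) {
    lml <- -0.5 * sum(yc * alpha) - sum(log(diag(f$L))) -
      length(x) / 2 * log(2 * pi)
  }
  structure(list(hyperparams = hp, train_x = x, train_y = y,
                 L = f$L, alpha = alpha, jitter = f$jitter,
                 log_marginal_likelihood = lml),
            class = "gp_model")
}

#' Build a GP model at fixed hyperparameters (no optimisation)
#'
#' @param x,y training data.
#' @param hp a [gp_hyperparams()]; its `constant_mean` is used as-is.
#' @return a `gp_model`.
#' @export
gp_model_fixed <- function(x, y, hp) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  new_gp_model(x, y, hp)
}

#' @export
print.gp_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(paste0("<gp_model n=%d: signal_variance=%.4g, length_scale=%.4g, ",
                     "noise_variance=%.4g, constant_mean=%.4g, lml=%.4g>\n"),
              length(x$train_x), hp$signal_variance, hp$length_scale,
              hp$noise_variance, hp$constant_mean,
              x$log_marginal_likelihood))
  invisible(x)
}

#' Predictive distribution at new inputs
#'
#' Exact GP posterior: mean `mu0 + k*' (K + sigma_n^2 I)^-1 yc` and latent
#' variance `k** - k*' (K + sigma_n^2 I)^-1 k*`.  The 95% band is
#' observation-level by default (adds the noise variance), so it should
#' envelop noisy replicate measurements.
#'
#' @param model a fitted `gp_model`.
#' @param x_star query inputs (vectorized).
#' @param level `"observation"` (default) or `"latent"` interval width.
#' @return data.frame with columns `x`, `mean`, `variance` (latent),
#'   `ci95_low`, `ci95_high`.
#' @export
gp_predict <- function(model, x_star, level = c("observation", "latent")) {
  stopifnot(inherits(model, "gp_model"))
  level <- match.arg(level)
  hp <- model$hyperparams
  ks <- rbf_kernel(model$train_x, x_star, hp)
  if (length(model$train_x) == 1L || length(x_star) == 1L) {
    ks <- matrix(ks, nrow = length(model$train_x))
  }
  mu <- hp$constant_mean + drop(crossprod(ks, model$alpha))
  v <- forwardsolve(model$L, ks)
  lat_var <- pmax(hp$signal_variance - colSums(v^2), 0)
  band_var <- lat_var + if (level == "observation") hp$noise_variance else 0
  data.frame(x = x_star, mean = mu, variance = lat_var,
             ci95_low = mu - 1.96 * sqrt(band_var),
             ci95_high = mu + 1.96 * sqrt(band_var))
}

#' Evaluate predictive accuracy on held-out data
#'
#' @param model a fitted `gp_model`.
#' @param test_x,test_y held-out inputs/outputs (non-empty; the outputs
#'   must not be constant or R-squared is undefined).
#' @return list with `r_squared`, `rmse` and `n_test`.
#' @export
gp_evaluate <- function(model, test_x, test_y) {
  stopifnot(length(test_x) == length(test_y))
  if (length(test_x) == 0) stop("empty test set", call. = FALSE)
  ss_tot <- sum((test_y - mean(test_y))^2)
  if (ss_tot == 0) {
    stop("zero-variance test outputs: R-squared undefined", call. = FALSE)
  }
  pred <- gp_predict(model, test_x)$mean
  ss_res <- sum((test_y - pred)^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((test_y - pred)^2)),
       n_test = length(test_x))
}

#' Time-series-aware k-fold cross-validation
#'
#' Splits the series into `k_folds` contiguous blocks along the input
#' order, fits on the complement of each block and evaluates on it.
#'
#' @param x,y full series (x should be sorted in time).
#' @param k_folds number of folds (default 5; requires n >= k_folds).
#' @param seed passed to each fold's [gp_fit()].
#' @param ... further arguments to [gp_fit()] (e.g. `n_restarts`).
#' @return list with `folds` (data.frame: `fold`, `r_squared`, `rmse`,
#'   `n_test`) and `summary` (mean and sd of the fold R-squared values).
#' @export
gp_crossvalidate <- function(x, y, k_folds = 5, seed = 1, ...) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < k_folds) stop("need n >= k_folds", call. = FALSE)
  fold_id <- cut(seq_len(n), breaks = k_folds, labels = FALSE)
  rows <- lapply(seq_len(k_folds), function(k) {
    test <- fold_id == k
    m <- gp_fit(x[!test], y[!test], seed = derive_seed(seed, paste0("cv/fold", k)),
                ...)
    ev <- gp_evaluate(m, x[test], y[test])
    data.frame(fold = k, r_squared = ev$r_squared, rmse = ev$rmse,
               n_test = ev$n_test)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       summary = list(mean_r_squared = mean(folds$r_squared),
                      sd_r_squared = stats::sd(folds$r_squared),
                      mean_rmse = mean(folds$rmse)))
}

#' Chronological holdout fit of the cohort force trajectory
#'
#' Fits one GP per handlebar channel on the earliest `split_fraction` of
#' the pooled longitudinal series and evaluates on the remaining, most
#' recent samples -- the forecasting use the model exists for.
#'
#' @param trajectory output of [cohort_force_trajectory()].
#' @param split_fraction training fraction (default 0.8).
#' @param n_restarts,seed,maxit passed to [gp_fit()].
#' @return list with one element per channel (`fsr1`, `fsr2`), each holding
#'   `model`, `holdout` (the [gp_evaluate()] report) and `split_fraction`.
#' @export
gp_trajectory_report <- function(trajectory, split_fraction = 0.8,
                                 n_restarts = 3, seed = 1, maxit = 60) {
  stopifnot(all(c("time_index", "fsr1_n", "fsr2_n") %in% names(trajectory)))
  n <- nrow(trajectory)
  n_train <- floor(split_fraction * n)
  out <- lapply(c(fsr1 = "fsr1_n", fsr2 = "fsr2_n"), function(col) {
    x <- trajectory$time_index
    y <- trajectory[[col]]
    m <- gp_fit(x[seq_len(n_train)], y[seq_len(n_train)],
                n_restarts = n_restarts, seed = seed, maxit = maxit)
    list(model = m,
         holdout = gp_evaluate(m, x[(n_train + 1):n], y[(n_train + 1):n]),
         split_fraction = split_fraction)
  })
  out
}
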