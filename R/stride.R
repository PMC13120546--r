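## Gait-cycle segmentation and stride-time variability comparison.

#' Construct a stride-interval series
#'
#' @param subject_id identifier.
#' @param group `"control"` or `"als_like"`.
#' @param intervals_s successive stride durations in seconds (all > 0).
#' @return an object of class `stride_intervals`.
#' @export
stride_intervals <- function(subject_id, group = c("control", "als_like"),
                             intervals_s) {
  group <- match.arg(group)
  if (length(intervals_s) == 0 || any(intervals_s <= 0)) {
    stop("intervals must be a non-empty vector of positive durations",
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, group = group,
                 intervals_s = as.numeric(intervals_s)),
            class = "stride_intervals")
}

#' Segment gait cycles from a periodic force signal
#'
#' Detects footfall peaks (local maxima with prominence at least
#' `prominence_fraction` of the signal range, separated by at least
#' `min_period_s`), then applies transient filtering: the first and last
#' detected cycles are dropped and any interval outside median +/- 3 MAD
#' (median absolute deviation) is removed as an artifact.
#'
#' @param x periodic force (or footswitch) signal.
#' @param fs sampling rate, Hz.
#' @param min_period_s minimum stride period (default 0.4 s, a human gait
#'   constraint).
#' @param prominence_fraction peak prominence floor as a fraction of the
#'   signal range (default 0.3).
#' @return list with `peak_times_s` (all retained peak times after
#'   endpoint removal), `intervals_s` (MAD-filtered stride intervals) and
#'   `n_removed` (intervals dropped by the MAD gate).  Empty (with a
#'   warning) when no peaks are found.
#' @export
segment_gait_cycles <- function(x, fs, min_period_s = 0.4,
                                prominence_fraction = 0.3) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("signal needs at least 3 samples", call. = FALSE)
  rng <- diff(range(x))
  empty <- list(peak_times_s = numeric(0), intervals_s = numeric(0),
                n_removed = 0L)
  if (rng == 0) {
    warning("constant signal: no gait cycles found")
    return(empty)
  }
  # local maxima (plateaus take their first sample)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) {
    warning("no local maxima: no gait cycles found")
    return(empty)
  }
  prom <- vapply(cand, function(i) peak_prominence(x, i, cand), numeric(1))
  keep <- cand[prom >= prominence_fraction * rng]
  if (!length(keep)) {
    warning("no peaks exceed the prominence floor")
    return(empty)
  }
  # enforce minimum separation greedily, tallest first
  keep <- keep[order(-x[keep])]
  min_gap <- min_period_s * fs
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel) || all(abs(sel - i) >= min_gap)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  if (length(sel) < 3) {
    warning("fewer than 3 peaks after separation filtering")
    return(empty)
  }
  sel <- sel[-c(1L, length(sel))]          # transient endpoint-cycle removal
  peak_times <- (sel - 1) / fs
  iv <- diff(peak_times)
  if (length(iv) >= 2) {
    med <- stats::median(iv)
    # scaled MAD, floored at one sample period: peak times are quantized to
    # the sampling grid, so a perfectly periodic signal has MAD 0 yet its
    # intervals still wobble by +/- one sample
    mad_iv <- max(stats::mad(iv), 1 / fs)
    ok <- abs(iv - med) <= 3 * mad_iv
  } else {
    ok <- rep(TRUE, length(iv))
  }
  list(peak_times_s = peak_times, intervals_s = iv[ok],
       n_removed = sum(!ok))
}

## topographic prominence of peak i among candidate peaks: height above the
## higher of the two minima separating it from the nearest higher ground
peak_prominence <- function(x, i, cand) {
  h <- x[i]
  left <- x[seq_len(i - 1)]
  right <- x[seq(i + 1, length(x))]
  higher_l <- which(left > h)   # strictly higher: plateau samples of the
  higher_r <- which(right > h)  # same peak must not zero its prominence
  base_l <- if (length(higher_l)) min(left[seq(max(higher_l), i - 1)]) else min(left)
  base_r <- if (length(higher_r)) {
    min(right[seq_len(min(higher_r))])
  } else {
    min(right)
  }
  h - max(base_l, base_r)
}

#' Unbiased sample variance of stride intervals
#'
#' @param intervals a [stride_intervals()] object or a numeric vector of
#'   durations (>= 2 values).
#' @return variance in s^2.
#' @export
stride_time_variance <- function(intervals) {
  iv <- if (inherits(intervals, "stride_intervals")) {
    intervals$intervals_s
  } else {
    intervals
  }
  if (length(iv) < 2) stop("variance needs at least 2 intervals", call. = FALSE)
  stats::var(iv)
}

#' Compare stride-time variance between two groups
#'
#' Group-level mean of per-subject interval variances, their ratio
#' (larger over smaller), and a median-centred Levene test for equality of
#' variances on the pooled intervals (robust to non-normal stride
#' distributions).
#'
#' @param a,b lists of [stride_intervals()] objects, one per subject
#'   (>= 2 intervals each; at least one subject per group).
#' @return an object of class `variance_comparison`: `var_group_a`,
#'   `var_group_b` (mean within-subject variances), `ratio`,
#'   `test_statistic`, `p_value`, and the group labels.
#' @export
compare_groups <- function(a, b) {
  check <- function(g, name) {
    if (!is.list(g) || !length(g) ||
        !all(vapply(g, inherits, logical(1), "stride_intervals"))) {
      stop(sprintf("`%s` must be a non-empty list of stride_intervals", name),
           call. = FALSE)
    }
    if (any(vapply(g, function(s) length(s$intervals_s), integer(1)) < 2)) {
      stop("every subject needs >= 2 intervals", call. = FALSE)
    }
  }
  check(a, "a"); check(b, "b")
  var_a <- mean(vapply(a, stride_time_variance, numeric(1)))
  var_b <- mean(vapply(b, stride_time_variance, numeric(1)))
  pooled <- data.frame(
    interval_s = c(unlist(lapply(a, `[[`, "intervals_s")),
                   unlist(lapply(b, `[[`, "intervals_s"))),
    grp = factor(rep(c("a", "b"),
                 c(sum(vapply(a, function(s) length(s$intervals_s), integer(1))),
                   sum(vapply(b, function(s) length(s$intervals_s), integer(1)))))))
  lev <- car::leveneTest(interval_s ~ grp, data = pooled, center = stats::median)
  structure(
    list(var_group_a = var_a, var_group_b = var_b,
         ratio = max(var_a, var_b) / min(var_a, var_b),
         test_statistic = lev$`F value`[1], p_value = lev$`Pr(>F)`[1],
         group_a = a[[1]]$group, group_b = b[[1]]$group,
         n_a = length(a), n_b = length(b)),
    class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf(paste0("Stride-time variance: %s %.5f s^2 vs %s %.5f s^2 ",
                     "(ratio %.2f)\nLevene (median-centred): F = %.3f, p = %.3g\n"),
              x$group_a, x$var_group_a, x$group_b, x$var_group_b, x$ratio,
              x$test_statistic, x$p_value))
  invisible(x)
}
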