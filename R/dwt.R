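## Periodized discrete wavelet transform (Daubechies db4), authored
## in-package: the analysis/synthesis pair uses circular convolution with
## dyadic downsampling ("periodization" convention), which keeps the
## transform orthonormal and exactly invertible at every even length.

DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- rev(DB4_DEC_LO)
DB4_REC_HI <- c(-0.010597401785069032, -0.0328830116668852,
                0.030841381835560764, 0.18703481171909309,
                -0.027983769416859854, -0.6308807679298589,
                0.7148465705529157, -0.2303778133088965)

## one periodized analysis step: even-length x -> list(cA, cD), each n/2
dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0, n >= 2)
  n2 <- n / 2
  cA <- numeric(n2)
  cD <- numeric(n2)
  k2 <- 2 * (seq_len(n2) - 1)
  for (m in 0:7) {
    idx <- ((k2 + 4 - m) %% n) + 1
    cA <- cA + DB4_DEC_LO[m + 1] * x[idx]
    cD <- cD + DB4_DEC_HI[m + 1] * x[idx]
  }
  list(cA = cA, cD = cD)
}

## inverse of dwt_step
idwt_step <- function(cA, cD) {
  n2 <- length(cA)
  stopifnot(length(cD) == n2)
  n <- 2 * n2
  u <- numeric(n); u[seq(1, n, by = 2)] <- cA
  v <- numeric(n); v[seq(1, n, by = 2)] <- cD
  x <- numeric(n)
  i0 <- seq_len(n) - 1
  for (m in 0:7) {
    idx <- ((i0 - m + 3) %% n) + 1
    x <- x + DB4_REC_LO[m + 1] * u[idx] + DB4_REC_HI[m + 1] * v[idx]
  }
  x
}

## multi-level decomposition; returns list(approx, details=list(d1..dL))
## with details[[1]] the finest level.  Length must be divisible by 2^levels.
dwt_db4 <- function(x, levels) {
  stopifnot(levels >= 1, length(x) %% 2^levels == 0)
  details <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(cur)
    details[[l]] <- s$cD
    cur <- s$cA
  }
  list(approx = cur, details = details)
}

idwt_db4 <- function(decomp) {
  cur <- decomp$approx
  for (l in rev(seq_along(decomp$details))) {
    cur <- idwt_step(cur, decomp$details[[l]])
  }
  cur
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
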