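#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream key
#'
#' All randomness in the package flows from a single master seed.  Each
#' generated stream (subject x day x modality, restart index, fold, ...)
#' draws its own sub-seed so that regenerating one stream never perturbs
#' another.  The derivation is a 32-bit FNV-1a hash of the key string mixed
#' with the master seed, reduced modulo 2^31 - 1 so the result is a valid
#' R integer seed.
#'
#' @param master integer master seed.
#' @param key character scalar identifying the stream, e.g. "S01/day03/force".
#' @return an integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  bytes <- utf8ToInt(paste0(format(master, scientific = FALSE), "|", key))
  as.integer(fnv1a32(bytes) %% 2147483647)
}

## round half away from zero at d decimals (report convention; R's round()
## uses half-to-even which disagrees with printed clinical tables)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_time_ordered <- function(t, what = "stream") {
  if (is.unsorted(t, strictly = FALSE)) {
    stop(sprintf("%s timestamps must be non-decreasing", what), call. = FALSE)
  }
  invisible(t)
}

## 32-bit FNV-1a over a byte vector, carried exactly in doubles
## (values exceed .Machine$integer.max so bitwXor cannot be used directly;
##  the xor only ever touches the low byte because inputs are bytes)
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

## FNV-1a hex digest of a character scalar; used for config provenance
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- fnv1a32(utf8ToInt(x))
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

## strip S3 classes recursively so any structure serialises as plain JSON
plainify <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), plainify)
  } else if (is.factor(x)) {
    as.character(x)
  } else {
    attr(x, "class") <- NULL
    x
  }
}

## with_seed: evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
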