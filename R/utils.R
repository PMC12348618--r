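# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a base seed and an integer offset.
#' Keeps results inside the 32-bit integer range so set.seed() accepts them.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483587)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

#' Column z-score. `center_only` leaves the scale untouched.
#' @noRd
zscore <- function(x, sample_sd = TRUE) {
  x <- as.numeric(x)
  s <- if (sample_sd) sd(x) else sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("cannot z-score a constant vector", call. = FALSE)
  (x - mean(x)) / s
}

#' FNV-1a hash of a character string, returned as 8 hex digits.
#' Used only for manifest provenance stamps, not for security.
#' @noRd
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    # 32-bit multiply by FNV prime 16777619, done in double with explicit mod
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Moving average with a centred window; edges use the available samples.
#' @noRd
moving_average <- function(x, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - half)
    hi <- min(n, t + width - 1L - half)
    out[t] <- mean(x[lo:hi])
  }
  out
}

#' Rescale a vector linearly onto [lo, hi].
#' @noRd
rescale_range <- function(x, lo = 0, hi = 1) {
  r <- range(x)
  if (diff(r) == 0) return(rep((lo + hi) / 2, length(x)))
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Near-equal fold ids for n items over k folds (caller shuffles first).
#' @noRd
fold_ids <- function(n, k) {
  rep_len(seq_len(k), n)
}

as_matrix_list <- function(Y) {
  if (is.matrix(Y)) list(Y) else if (is.list(Y)) Y else stop("expected a matrix or list of matrices")
}
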