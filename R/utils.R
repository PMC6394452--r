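# Internal helpers: seed derivation, unit conversion, small numerics.

# Deterministic child seed from a master seed and a stream of small tags.
# Keeps results reproducible and the real / permuted-label analyses on
# independent streams. Result always fits in a 32-bit signed integer.
derive_seed <- function(master, ...) {
  tags <- c(...)
  h <- as.double(master) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

# Convert milliseconds to a whole number of samples; non-integral results
# are an error because silent rounding would change the analysis grid.
ms_to_samples <- function(ms, sampling_rate_hz, what = "value") {
  s <- ms * sampling_rate_hz / 1000
  if (abs(s - round(s)) > 1e-8) {
    stop(sprintf("%s of %g ms is not a whole number of samples at %g Hz (%.4f samples)",
                 what, ms, sampling_rate_hz, s), call. = FALSE)
  }
  as.integer(round(s))
}

# z-standardise a vector; constant input yields all zeros with a warning
# (degenerate rule) rather than NaN.
zscore_safe <- function(x, warn = TRUE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (warn) warning("zero standard deviation; z-scores set to 0", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# Fisher-Z (atanh) with |r| clamped away from 1 to avoid infinities.
fisher_z <- function(r) {
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  atanh(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
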