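# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(x^2))

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state, so that
#' deterministic draws (subjects, recordings, rotations) do not perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: a multiplicative hash of the base seed and
# any number of non-negative integer ids. Stays inside the 32-bit signed range.
derive_seed <- function(base, ...) {
  ids <- c(...)
  h <- (as.numeric(base) %% 2147483647) + 1
  for (id in ids) {
    h <- (h * 69069 + as.numeric(id) + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

# Zero-phase Butterworth filtering. The series mean is removed before the
# forward-backward pass (and restored for low-pass filters): a constant
# offset would otherwise excite edge transients on short clips, and for a
# high-pass the DC belongs in the stopband anyway.
zero_phase <- function(x, filt, keep_mean = FALSE) {
  mu <- mean(x)
  y <- signal::filtfilt(filt, x - mu)
  if (keep_mean) y + mu else y
}

# Central moments with n denominator; used by several feature ops.
central_moments <- function(x) {
  mu <- mean(x)
  d <- x - mu
  list(mean = mu, m2 = mean(d^2), m3 = mean(d^3), m4 = mean(d^4))
}

# Standardized skewness / excess kurtosis with a degenerate flag for
# zero-variance input (returned as 0 rather than NaN).
skew_kurt <- function(x, tol = 1e-24) {
  m <- central_moments(x)
  if (m$m2 < tol) {
    list(skew = 0, kurtosis = 0, degenerate = TRUE)
  } else {
    list(
      skew = m$m3 / m$m2^1.5,
      kurtosis = m$m4 / m$m2^2 - 3,
      degenerate = FALSE
    )
  }
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
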