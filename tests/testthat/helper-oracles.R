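# Independent brute-force oracles and shared lazily-built fixtures.

# Sample entropy by direct double-loop template counting (Richman-Moorman
# convention: both counts over templates 1..N-m, self-matches excluded,
# Chebyshev distance, match when distance <= r).
sampen_oracle <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  k <- n - m
  a <- 0L
  b <- 0L
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) b <- b + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) a <- a + 1L
    }
  }
  if (b == 0) return(log(k * (k - 1) / 2))
  if (a == 0) return(log(b))
  -log(a / b)
}

# Cross-correlation by explicit lag loop.
xcorr_oracle <- function(a, b, fs = 62.5) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  len <- length(a)
  lags <- -(len - 1):(len - 1)
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a0[1:(len - k)] * b0[(1 + k):len])
    else sum(a0[(1 - k):len] * b0[1:(len + k)])
  }, 0)
  cc <- cc / sqrt(sum(a0^2) * sum(b0^2))
  pk <- max(cc)
  cand <- which(cc == pk)
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  c(peak = pk, lag = lags[best] / fs)
}

# AUROC by exhaustive positive-negative pair counting, ties worth 1/2.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Window counting by explicit enumeration of valid start indices.
count_windows_oracle <- function(n, len, step) {
  count <- 0L
  s <- 1L
  while (s + len - 1L <= n) {
    count <- count + 1L
    s <- s + step
  }
  count
}

# ---- shared fixtures (built once per test run) ----------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small single-location cohort used by preprocessing/feature tests.
small_hand_cohort <- function() {
  fixture("small_hand", function() {
    simulate_cohort(cohort_config(
      n_subjects = 4, tasks = default_tasks()[c(1, 3), ],
      n_sessions_day1 = 2, include_day2 = FALSE, day2_subjects = 0,
      duration_s = 10, locations = "hand", rng_seed = 11
    ))
  })
}

# Harder, heterogeneous cohort with day 2, used for ordering tests.
ordering_cohort <- function() {
  fixture("ordering", function() {
    simulate_cohort(cohort_config(
      n_subjects = 10, tasks = default_tasks()[c(1, 3, 8, 11), ],
      n_sessions_day1 = 3, include_day2 = TRUE, day2_subjects = 10,
      duration_s = 15, locations = "hand", brady_atten = 0.85,
      subject_amp_sd = 0.6, group_expression = c(gross_motor = 0.4),
      rng_seed = 31
    ))
  })
}

# One filtered 6-channel clip (tremor path).
one_filtered_clip <- function() {
  fixture("one_clip", function() {
    co <- small_hand_cohort()
    cs <- filter_clips(assemble_dataset(co, "hand"), "tremor")
    list(clip = cs$clips[[1]], fs = cs$fs)
  })
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
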