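fs <- 62.5
tt <- (0:311) / fs

test_that("a single-sensor clip yields exactly 56 named, finite features", {
  oc <- one_filtered_clip()
  fv <- extract_feature_vector(oc$clip, oc$fs)
  expect_length(fv, 56)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_error(extract_feature_vector(oc$clip[, 1:4], oc$fs), "multiple of 6")
})

test_that("multi-sensor clips concatenate one 56-block per sensor", {
  oc <- one_filtered_clip()
  combo <- cbind(oc$clip, oc$clip, oc$clip)
  colnames(combo) <- paste(rep(c("hand", "forearm", "thigh"), each = 6),
                           rep(c("accX", "accY", "accZ",
                                 "gyroX", "gyroY", "gyroZ"), 3), sep = "_")
  fv <- extract_feature_vector(combo, oc$fs)
  expect_length(fv, 168)
  expect_identical(names(fv),
                   feature_names(c("hand", "forearm", "thigh")))
  expect_equal(unname(fv[1:56]), unname(fv[57:112]))
})

test_that("axis statistics match closed forms", {
  st <- axis_stats(c(0, 1, 2, 3))
  expect_equal(unname(st["range"]), 3)
  sym <- sin(2 * pi * (0:99) / 100)
  expect_lt(abs(axis_stats(sym)["skew"]), 1e-12)
  set.seed(10)
  big <- axis_stats(rnorm(1e5))
  expect_lt(abs(big[["kurtosis"]]), 0.2)
  flat <- axis_stats(rep(2, 10))
  expect_equal(unname(flat[c("skew", "kurtosis")]), c(0, 0))
  expect_true(attr(flat, "degenerate"))
})

test_that("cross-correlation peak/lag match the brute-force oracle", {
  set.seed(3)
  a <- rnorm(80)
  self <- xcorr_features(a, a, fs)
  expect_equal(unname(self["peak"]), 1)
  expect_equal(unname(self["lag"]), 0)

  b <- c(rep(0, 10), a[1:70])
  del <- xcorr_features(a, b, fs)
  expect_equal(unname(del["lag"]), 10 / fs)
  expect_equal(unname(del["lag"]), 0.16)

  s5 <- sin(2 * pi * 5 * tt)
  flip <- xcorr_features(s5, -s5, fs)
  expect_gt(unname(flip["peak"]), 0.95)          # max at a half-period shift
  expect_lt(abs(abs(unname(flip["lag"])) - 0.5 / 5), 1 / fs)

  for (i in 1:100) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    y <- if (i %% 3 == 0) x + rnorm(n, 0, 0.5) else rnorm(n)
    got <- xcorr_features(x, y, fs)
    want <- xcorr_oracle(x, y, fs)
    expect_lt(abs(got[["peak"]] - want[["peak"]]), 1e-10)
    expect_lt(abs(got[["lag"]] - want[["lag"]]), 1e-10)
  }

  zv <- xcorr_features(rep(1, 50), rnorm(50), fs)
  expect_equal(as.numeric(zv), c(0, 0))
  expect_true(attr(zv, "degenerate"))
})

test_that("dominant frequency recovers tones within one bin", {
  expect_equal(as.numeric(dominant_frequency(sin(2 * pi * 5 * tt), fs)), 5,
               tolerance = 0.25)
  expect_equal(as.numeric(dominant_frequency(sin(2 * pi * 20 * tt), fs)), 20,
               tolerance = 0.25)
  two <- sin(2 * pi * 2 * tt) + 2 * sin(2 * pi * 5 * tt)
  expect_equal(as.numeric(dominant_frequency(two, fs)), 5, tolerance = 0.25)
  flat <- dominant_frequency(rep(1, 312), fs)
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("spectral moments treat the spectrum as a distribution", {
  pm <- psd_moments(sin(2 * pi * 5 * tt), fs)
  expect_equal(unname(pm["psd_mean"]), 5, tolerance = 0.25)
  expect_lt(unname(pm["psd_var"]), 0.5)
  two <- sin(2 * pi * 4 * tt) + sin(2 * pi * 6 * tt)
  pm2 <- psd_moments(two, fs)
  expect_equal(unname(pm2["psd_mean"]), 5, tolerance = 0.25)
  expect_lt(abs(unname(pm2["psd_skew"])), 0.3)   # symmetric two-tone spectrum
})

test_that("jerk moments follow the derivative closed forms", {
  z <- jerk_moments(matrix(1, 100, 3), fs)
  expect_equal(as.numeric(z), c(0, 0, 0, 0))
  expect_true(attr(z, "degenerate"))

  ramp <- cbind((0:99) / fs, rep(0, 100), rep(0, 100))  # slope 1 unit/s
  jr <- jerk_moments(ramp, fs)
  expect_equal(unname(jr["jerk_mean"]), 1, tolerance = 1e-9)
  expect_equal(unname(jr["jerk_var"]), 0, tolerance = 1e-12)

  amp <- 0.3
  s5 <- cbind(amp * sin(2 * pi * 5 * tt), rep(0, 312), rep(0, 312))
  jm <- jerk_moments(s5, fs)
  expect_equal(unname(jm["jerk_mean"]), (2 / pi) * amp * 2 * pi * 5,
               tolerance = 0.05 * (2 / pi) * amp * 2 * pi * 5)
})

test_that("relative magnitude is the RMS about the clip's own baseline", {
  expect_equal(relative_magnitude(matrix(1, 50, 3)), 0)
  x <- cbind(1 + sin(2 * pi * 5 * tt), rep(0, 312), rep(0, 312))
  expect_equal(relative_magnitude(x), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(relative_magnitude(2 * x) / relative_magnitude(x), 2,
               tolerance = 1e-9)
})

test_that("sample entropy matches the double-loop oracle exactly", {
  ramp <- seq(0, 1, length.out = 100)
  expect_equal(as.numeric(sample_entropy(ramp)), 0)

  s5 <- sin(2 * pi * 5 * tt)
  set.seed(8)
  expect_lt(as.numeric(sample_entropy(s5)),
            as.numeric(sample_entropy(sample(s5))))

  set.seed(12)
  for (i in 1:100) {
    n <- sample(30:150, 1)
    x <- if (i %% 4 == 0) sin(2 * pi * 3 * (1:n) / n) + rnorm(n, 0, 0.2)
         else rnorm(n)
    expect_lt(abs(as.numeric(sample_entropy(x)) - sampen_oracle(x)), 1e-10)
  }

  zv <- sample_entropy(rep(3, 50))
  expect_equal(as.numeric(zv), 0)
  expect_true(attr(zv, "degenerate"))
})

test_that("features scale (or stay invariant) with amplitude as designed", {
  oc <- one_filtered_clip()
  f1 <- extract_feature_vector(oc$clip, oc$fs)
  f2 <- extract_feature_vector(oc$clip * 2, oc$fs)
  lin <- c("acc_range_x", "acc_rel_magnitude", "acc_jerk_mean",
           "gyro_range_y", "gyro_jerk_mean")
  for (nm in lin) expect_equal(unname(f2[nm] / f1[nm]), 2, tolerance = 1e-6)
  inv <- c("acc_skew_x", "acc_kurtosis_y", "acc_dom_freq", "acc_sampen_x",
           "gyro_sampen_z", "gyro_dom_freq")
  for (nm in inv) expect_equal(unname(f2[nm]), unname(f1[nm]),
                               tolerance = 1e-6)
})

test_that("an all-zero clip returns a finite flagged vector", {
  clip <- matrix(0, 312, 6)
  colnames(clip) <- c("accX", "accY", "accZ", "gyroX", "gyroY", "gyroZ")
  fv <- extract_feature_vector(clip, fs)
  expect_true(all(is.finite(fv)))
  expect_gt(length(attr(fv, "degenerate")), 0)
})

test_that("tremor-positive clips separate from symptom-free clips in frequency", {
  cfg <- cohort_config(n_subjects = 8, tasks = default_tasks()[c(1, 3, 4), ],
                       n_sessions_day1 = 3, include_day2 = FALSE,
                       day2_subjects = 0, duration_s = 10,
                       locations = "hand", tremor_amp = 0.25, rng_seed = 19)
  co <- simulate_cohort(cfg)
  cs <- filter_clips(assemble_dataset(co, "hand"), "tremor")
  ds <- extract_features(cs)
  expect_false(any(!is.finite(ds$x)))
  pos <- ds$x[ds$meta$score_tremor >= 2, "acc_dom_freq"]
  neg <- ds$x[ds$meta$score_tremor == 0, "acc_dom_freq"]
  expect_gte(length(pos), 15)
  expect_gte(length(neg), 30)
  # after per-axis high-passing, the magnitude of a zero-mean oscillation
  # concentrates at the rectified harmonic: twice the 4-6 Hz tremor band
  expect_within(mean(pos), 8, 12)
  tt_ <- stats::t.test(pos, neg)
  expect_lt(tt_$p.value, 0.01)
  # the orientation-referenced magnitude retains the 4-6 Hz fundamental
  raw <- assemble_dataset(co, "hand")
  pos_clips <- which(raw$meta$score_tremor >= 2)
  doms <- vapply(utils::head(pos_clips, 50), function(i) {
    as.numeric(dominant_frequency(
      gravity_free_magnitude(raw$clips[[i]], raw$fs), raw$fs))
  }, 0)
  expect_gte(mean(doms >= 4 & doms <= 6), 0.9)
})
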