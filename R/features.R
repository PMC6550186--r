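# 56-dimensional feature representation of a filtered clip: 28 features per
# modality (accelerometer, gyroscope), covering per-axis distribution shape,
# inter-axis cross-correlation, spectral location and shape of the magnitude,
# jerk statistics and per-axis sample entropy.

.axis_names <- c("x", "y", "z")
.pair_names <- c("xy", "xz", "yz")

# Welch-averaged periodogram: Hann-windowed 50%-overlapping segments,
# zero-padded for a frequency grid finer than 0.25 Hz.
welch_psd <- function(x, fs, seg_len = NULL, nfft = 1024L) {
  x <- x - mean(x)
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, 156L)
  seg_len <- min(seg_len, n)
  nfft <- max(nfft, seg_len)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  p <- 0
  for (s in starts) {
    xs <- c(x[s:(s + seg_len - 1L)] * win, rep(0, nfft - seg_len))
    p <- p + Mod(fft(xs))^2
  }
  nf <- nfft %/% 2L + 1L
  list(freq = (0:(nf - 1L)) * fs / nfft,
       power = p[seq_len(nf)] / length(starts))
}

#' Per-axis distribution statistics
#'
#' Range (max - min), standardized skewness and excess kurtosis (Fisher
#' convention: a normal sample has kurtosis near 0). A zero-variance series
#' returns skewness and kurtosis of 0 with a `degenerate` attribute.
#'
#' @param x numeric vector with at least 4 samples.
#' @return Named numeric `c(range, skew, kurtosis)`.
#' @export
axis_stats <- function(x) {
  stopifnot(length(x) >= 4)
  sk <- skew_kurt(x)
  out <- c(range = max(x) - min(x), skew = sk$skew, kurtosis = sk$kurtosis)
  attr(out, "degenerate") <- sk$degenerate
  out
}

#' Normalized cross-correlation peak and lag between two channels
#'
#' Both series are mean-subtracted; the cross-correlation
#' `c(k) = sum_t a_t b_(t+k)` over all lags in `+-(L-1)` is normalized by the
#' product of the series norms. The peak is the maximum value and the lag is
#' its position in seconds; exact ties are broken toward the smallest
#' absolute lag.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param fs sampling rate in Hz (converts the lag to seconds).
#' @return Named numeric `c(peak, lag)`; a zero-variance channel gives
#'   `c(0, 0)` with a `degenerate` attribute.
#' @export
xcorr_features <- function(a, b, fs = 62.5) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  len <- length(a)
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  na <- sqrt(sum(a0^2))
  nb <- sqrt(sum(b0^2))
  if (na < 1e-12 || nb < 1e-12) {
    out <- c(peak = 0, lag = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cc <- convolve(b0, a0, conj = TRUE, type = "open") / (na * nb)
  lags <- -(len - 1L):(len - 1L)
  peak <- max(cc)
  cand <- which(cc == peak)
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  out <- c(peak = peak, lag = lags[best] / fs)
  attr(out, "degenerate") <- FALSE
  out
}

#' Dominant frequency of a magnitude series
#'
#' Argmax of the Welch-averaged periodogram of the mean-subtracted series,
#' searched above 0.25 Hz; zero padding gives a frequency grid finer than
#' 0.25 Hz.
#'
#' @param x numeric vector, at least 64 samples.
#' @param fs sampling rate in Hz.
#' @return Dominant frequency in Hz; an all-constant series returns 0 with a
#'   `degenerate` attribute.
#' @export
dominant_frequency <- function(x, fs = 62.5) {
  stopifnot(length(x) >= 64)
  if (max(x) - min(x) < 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  psd <- welch_psd(x, fs)
  keep <- psd$freq > 0.25
  structure(psd$freq[keep][which.max(psd$power[keep])], degenerate = FALSE)
}

#' Spectral moments of a magnitude series
#'
#' The normalized power spectrum is treated as a probability distribution
#' over frequency; returns its mean (Hz), variance (Hz^2), skewness and
#' excess kurtosis.
#'
#' @inheritParams dominant_frequency
#' @return Named numeric `c(psd_mean, psd_var, psd_skew, psd_kurt)`;
#'   zero total power gives all zeros with a `degenerate` attribute.
#' @export
psd_moments <- function(x, fs = 62.5) {
  stopifnot(length(x) >= 64)
  psd <- welch_psd(x, fs)
  tot <- sum(psd$power)
  if (tot < 1e-20) {
    out <- c(psd_mean = 0, psd_var = 0, psd_skew = 0, psd_kurt = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- psd$power / tot
  f <- psd$freq
  m <- sum(p * f)
  v <- sum(p * (f - m)^2)
  if (v < 1e-12) {
    out <- c(psd_mean = m, psd_var = v, psd_skew = 0, psd_kurt = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- c(psd_mean = m, psd_var = v,
           psd_skew = sum(p * (f - m)^3) / v^1.5,
           psd_kurt = sum(p * (f - m)^4) / v^2 - 3)
  attr(out, "degenerate") <- FALSE
  out
}

#' Moments of the jerk magnitude
#'
#' Jerk is the first difference of each axis times the sampling rate (units
#' per second); its per-sample Euclidean norm across the three axes is
#' summarized by mean, variance, skewness and excess kurtosis.
#'
#' @param x numeric matrix with 3 columns (axes) and at least 5 rows.
#' @param fs sampling rate in Hz.
#' @return Named numeric `c(jerk_mean, jerk_var, jerk_skew, jerk_kurt)`;
#'   constant channels give all zeros with a `degenerate` attribute.
#' @export
jerk_moments <- function(x, fs = 62.5) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3, nrow(x) >= 5)
  j <- diff(x) * fs
  jm <- sqrt(rowSums(j^2))
  if (max(jm) < 1e-12) {
    out <- c(jerk_mean = 0, jerk_var = 0, jerk_skew = 0, jerk_kurt = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sk <- skew_kurt(jm)
  out <- c(jerk_mean = mean(jm), jerk_var = mean((jm - mean(jm))^2),
           jerk_skew = sk$skew, jerk_kurt = sk$kurtosis)
  attr(out, "degenerate") <- sk$degenerate
  out
}

#' Relative movement magnitude
#'
#' Root-mean-square of the mean-subtracted Euclidean magnitude of the three
#' axes: the intensity of movement relative to the clip's own baseline.
#' Scales linearly with signal amplitude.
#'
#' @param x numeric matrix with 3 columns and at least 2 rows.
#' @return A single non-negative number.
#' @export
relative_magnitude <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3, nrow(x) >= 2)
  mag <- sqrt(rowSums(x^2))
  rms(mag - mean(mag))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B) where B counts pairs of length-`m` templates
#' within Chebyshev distance `r` and A the pairs whose length-`m+1`
#' extensions still match; self-matches are excluded and both counts run over
#' templates 1..N-m. Low values indicate a regular (e.g. rhythmic) signal.
#' If no length-`m+1` pair matches, the capped value `ln(B)` is returned; if
#' no length-`m` pair matches, `ln` of the maximum countable number of pairs.
#'
#' @param x numeric vector with at least `m + 2` samples.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return Sample entropy (non-negative); a zero-variance series returns 0
#'   with a `degenerate` attribute.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  stopifnot(n >= m + 2)
  if (sd(x) < 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  d <- abs(outer(x, x, "-"))
  dm <- d[seq_len(n - 1L), seq_len(n - 1L)]
  dm <- pmax(dm, d[2:n, 2:n])
  if (m > 2L) {
    for (k in 3:m) dm[seq_len(n - k + 1L), seq_len(n - k + 1L)] <-
        pmax(dm[seq_len(n - k + 1L), seq_len(n - k + 1L)], d[k:n, k:n])
    dm <- dm[seq_len(n - m + 1L), seq_len(n - m + 1L)]
  }
  kk <- n - m
  dmk <- dm[seq_len(kk), seq_len(kk)]
  dm1 <- pmax(dmk, d[(m + 1L):n, (m + 1L):n])
  b <- (sum(dmk <= r) - kk) / 2            # exclude self-matches (diagonal)
  a <- (sum(dm1 <= r) - kk) / 2
  max_pairs <- kk * (kk - 1) / 2
  if (b == 0) return(structure(log(max_pairs), degenerate = TRUE))
  if (a == 0) return(structure(log(b), degenerate = TRUE))
  structure(-log(a / b), degenerate = FALSE)
}

# 28 features of one 3-axis modality block.
modality_features <- function(x3, fs) {
  st <- lapply(1:3, function(j) axis_stats(x3[, j]))
  xc <- list(xcorr_features(x3[, 1], x3[, 2], fs),
             xcorr_features(x3[, 1], x3[, 3], fs),
             xcorr_features(x3[, 2], x3[, 3], fs))
  mag <- sqrt(rowSums(x3^2))
  dfq <- dominant_frequency(mag, fs)
  rmg <- relative_magnitude(x3)
  pm <- psd_moments(mag, fs)
  jm <- jerk_moments(x3, fs)
  se <- lapply(1:3, function(j) sample_entropy(x3[, j]))
  vals <- c(
    vapply(st, `[[`, 0, "range"),
    vapply(st, `[[`, 0, "skew"),
    vapply(st, `[[`, 0, "kurtosis"),
    vapply(xc, `[[`, 0, "peak"),
    vapply(xc, `[[`, 0, "lag"),
    as.numeric(dfq), rmg, unname(pm), unname(jm),
    vapply(se, as.numeric, 0)
  )
  deg <- c(
    rep(FALSE, 3),
    vapply(st, function(s) isTRUE(attr(s, "degenerate")), TRUE),
    vapply(st, function(s) isTRUE(attr(s, "degenerate")), TRUE),
    vapply(xc, function(s) isTRUE(attr(s, "degenerate")), TRUE),
    vapply(xc, function(s) isTRUE(attr(s, "degenerate")), TRUE),
    isTRUE(attr(dfq, "degenerate")), FALSE,
    rep(isTRUE(attr(pm, "degenerate")), 4),
    rep(isTRUE(attr(jm, "degenerate")), 4),
    vapply(se, function(s) isTRUE(attr(s, "degenerate")), TRUE)
  )
  list(values = vals, degenerate = deg)
}

modality_feature_names <- function() {
  c(paste0("range_", .axis_names), paste0("skew_", .axis_names),
    paste0("kurtosis_", .axis_names), paste0("xcorr_peak_", .pair_names),
    paste0("xcorr_lag_", .pair_names), "dom_freq", "rel_magnitude",
    "psd_mean", "psd_var", "psd_skew", "psd_kurt",
    "jerk_mean", "jerk_var", "jerk_skew", "jerk_kurt",
    paste0("sampen_", .axis_names))
}

#' Names of the 56 clip features
#'
#' @param sensors optional character vector of sensor block labels; if given,
#'   names are prefixed per sensor (one 56-feature block each).
#' @return Character vector of feature names in extraction order.
#' @export
feature_names <- function(sensors = NULL) {
  base <- c(paste0("acc_", modality_feature_names()),
            paste0("gyro_", modality_feature_names()))
  if (is.null(sensors)) return(base)
  unlist(lapply(sensors, function(s) paste(s, base, sep = "_")),
         use.names = FALSE)
}

#' Extract the feature vector of one clip
#'
#' Computes 28 features per modality (accelerometer, gyroscope) per sensor:
#' per-axis range / skewness / kurtosis, pairwise cross-correlation peaks and
#' lags, dominant frequency and spectral moments of the magnitude, relative
#' magnitude, jerk-magnitude moments, and per-axis sample entropy. A
#' single-sensor clip yields exactly 56 values; a clip carrying `k` sensors
#' yields `56 k`, one block per sensor.
#'
#' @param clip numeric matrix whose columns are sensor channels in blocks of
#'   six (acc x/y/z then gyro x/y/z), typically a [filter_clips()] output.
#' @param fs sampling rate in Hz.
#' @return Named numeric vector; the attribute `degenerate` names features
#'   computed from degenerate (e.g. zero-variance) input.
#' @export
extract_feature_vector <- function(clip, fs = 62.5) {
  clip <- as.matrix(clip)
  if (ncol(clip) %% 6L != 0L) {
    stop("clip must have a multiple of 6 channels (acc xyz + gyro xyz per sensor)",
         call. = FALSE)
  }
  n_sensors <- ncol(clip) %/% 6L
  sensors <- if (n_sensors == 1L) NULL else {
    nm <- colnames(clip)
    if (!is.null(nm)) {
      unique(sub("_(acc|gyro)[XYZ]$", "", nm))
    } else {
      paste0("sensor", seq_len(n_sensors))
    }
  }
  vals <- numeric(0)
  degs <- logical(0)
  for (s in seq_len(n_sensors)) {
    block <- clip[, (s - 1L) * 6L + 1:6, drop = FALSE]
    fa <- modality_features(block[, 1:3, drop = FALSE], fs)
    fg <- modality_features(block[, 4:6, drop = FALSE], fs)
    vals <- c(vals, fa$values, fg$values)
    degs <- c(degs, fa$degenerate, fg$degenerate)
  }
  names(vals) <- feature_names(sensors)
  attr(vals, "degenerate") <- names(vals)[degs]
  vals
}

#' Extract features for every clip in a set
#'
#' @param clip_set a filtered `clip_set` (see [filter_clips()]).
#' @return An object of class `pd_dataset`: feature matrix `x`
#'   (clips x features), clip metadata `meta`, and the symptom whose filter
#'   was applied.
#' @export
extract_features <- function(clip_set) {
  stopifnot(inherits(clip_set, "clip_set"))
  if (is.na(clip_set$filtered)) {
    stop("clip set must be filtered with filter_clips() before feature extraction",
         call. = FALSE)
  }
  p <- length(feature_names(if (length(clip_set$blocks) > 1)
    clip_set$blocks else NULL))
  x <- t(vapply(clip_set$clips, function(cl) {
    as.numeric(extract_feature_vector(cl, clip_set$fs))
  }, numeric(p)))
  colnames(x) <- feature_names(if (length(clip_set$blocks) > 1)
    clip_set$blocks else NULL)
  structure(list(x = x, meta = clip_set$meta, symptom = clip_set$filtered,
                 fs = clip_set$fs), class = "pd_dataset")
}

#' @export
print.pd_dataset <- function(x, ...) {
  cat(sprintf("<pd_dataset> %d clips x %d features (%s), %d subjects\n",
              nrow(x$x), ncol(x$x), x$symptom, length(unique(x$meta$subject))))
  invisible(x)
}

#' Feature manifest
#'
#' Definitions and units of the 56 clip features (28 per modality).
#'
#' @return Data frame with columns `name`, `units`, `definition`.
#' @export
feature_manifest <- function() {
  base <- data.frame(
    feature = modality_feature_names(),
    units = c(rep("signal units", 3), rep("-", 3), rep("-", 3), rep("-", 3),
              rep("s", 3), "Hz", "signal units", "Hz", "Hz^2", "-", "-",
              "signal units/s", "(signal units/s)^2", "-", "-", rep("-", 3)),
    definition = c(
      rep("max - min per axis", 3),
      rep("standardized third central moment per axis", 3),
      rep("excess kurtosis (normal = 0) per axis", 3),
      rep("maximum of the normalized cross-correlation over all lags", 3),
      rep("lag (s) of the cross-correlation maximum, ties toward 0", 3),
      "argmax (> 0.25 Hz) of the Welch periodogram of the mean-subtracted magnitude",
      "RMS of the mean-subtracted Euclidean magnitude",
      "spectral centroid: mean of the normalized power spectrum over frequency",
      "spectral variance", "spectral skewness", "spectral excess kurtosis",
      "mean of the jerk magnitude (first difference of per-axis signal x fs, Euclidean norm)",
      "variance of the jerk magnitude", "skewness of the jerk magnitude",
      "excess kurtosis of the jerk magnitude",
      rep("SampEn(m = 2, r = 0.2 sd), Chebyshev distance, self-matches excluded", 3)
    ),
    stringsAsFactors = FALSE
  )
  rbind(
    data.frame(name = paste0("acc_", base$feature), units = base$units,
               definition = paste("accelerometer:", base$definition)),
    data.frame(name = paste0("gyro_", base$feature), units = base$units,
               definition = paste("gyroscope:", base$definition))
  )
}
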