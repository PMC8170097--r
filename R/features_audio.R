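#' Paralinguistic feature family
#'
#' All acoustic features are computed from the waveform after resampling to
#' 16 kHz mono: temporal features from an intensity-based syllable-nuclei
#' detector, F0 statistics from an autocorrelation pitch tracker, 168
#' summary statistics over 14 mel-frequency cepstral coefficients and their
#' first/second frame differences, and 28 summary statistics over seven
#' frame-level spectral descriptors.  Frame parameters default to a 25 ms
#' window with a 10 ms step.
#'
#' @name features_audio
NULL

.EPS <- 1e-12

# moment skewness; kurtosis is excess kurtosis; both 0 for zero-variance
# series so that constant signals do not propagate NaN into the ML stage
moment_stats <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  m2 <- mean((x - m)^2)
  if (m2 < .EPS) c(mean = m, var = v, skewness = 0, kurtosis = 0)
  else c(mean = m, var = v,
         skewness = mean((x - m)^3) / m2^1.5,
         kurtosis = mean((x - m)^4) / m2^2 - 3)
}

## --- intensity, voicing, syllable nuclei ----------------------------------

frame_intensity_db <- function(x, rate, step = 0.010, frame_len = 0.025) {
  fr <- frame_signal(x, rate, frame_len, step)
  if (nrow(fr) == 0) return(numeric(0))
  10 * log10(rowMeans(fr^2) + .EPS)
}

# Autocorrelation F0 per frame.  40 ms frames (>= 2 periods at the 75 Hz
# floor), 10 ms step; a frame is voiced when its peak normalized
# autocorrelation in the 75-500 Hz lag band exceeds `voicing_threshold`
# and it carries non-negligible energy.
frame_f0 <- function(x, rate, floor_hz = 75, ceil_hz = 500,
                     voicing_threshold = 0.45, step = 0.010,
                     frame_len = 0.040) {
  fr <- frame_signal(x, rate, frame_len, step)
  if (nrow(fr) == 0) return(numeric(0))
  lag_min <- max(2L, floor(rate / ceil_hz))
  lag_max <- min(ncol(fr) - 2L, ceiling(rate / floor_hz))
  peak_rms <- sqrt(max(rowMeans(fr^2)))
  f0 <- rep(NA_real_, nrow(fr))
  for (i in seq_len(nrow(fr))) {
    s <- fr[i, ] - mean(fr[i, ])
    r0 <- sum(s^2)
    if (r0 < (.EPS + (1e-3 * peak_rms)^2 * length(s))) next
    ac <- vapply(lag_min:lag_max, function(l)
      sum(s[1:(length(s) - l)] * s[(l + 1):length(s)]), numeric(1)) / r0
    k <- which.max(ac)
    if (ac[k] < voicing_threshold) next
    # parabolic interpolation around the peak for sub-sample lag precision
    lag <- (lag_min:lag_max)[k]
    if (k > 1 && k < length(ac)) {
      d <- (ac[k - 1] - ac[k + 1]) / (2 * (ac[k - 1] - 2 * ac[k] + ac[k + 1]))
      if (is.finite(d) && abs(d) < 1) lag <- lag + d
    }
    f0[i] <- rate / lag
  }
  f0
}

# de Jong & Wempe style syllable nuclei: intensity peaks above a silence
# threshold (relative to the contour maximum) that rise at least
# `min_dip_db` above the preceding dip.
detect_syllable_nuclei <- function(intensity_db, step = 0.010,
                                   silence_db = -25, min_dip_db = 2) {
  if (length(intensity_db) < 3) return(integer(0))
  thr <- max(intensity_db) + silence_db
  n <- length(intensity_db)
  peaks <- which(diff(sign(diff(intensity_db))) == -2) + 1L
  peaks <- peaks[intensity_db[peaks] > thr]
  if (length(peaks) == 0) return(integer(0))
  keep <- integer(0)
  last_kept <- -Inf
  for (p in peaks) {
    lo <- if (length(keep)) keep[length(keep)] else 1L
    dip <- min(intensity_db[lo:p])
    if (intensity_db[p] - dip >= min_dip_db) {
      keep <- c(keep, p)
      last_kept <- p
    }
  }
  keep
}

# sounding intervals: frames above the silence threshold; gaps shorter
# than `min_pause_s` are bridged (they are articulatory, not pauses)
speaking_duration_s <- function(intensity_db, step = 0.010,
                                silence_db = -25, min_pause_s = 0.3) {
  if (length(intensity_db) == 0) return(0)
  sounding <- intensity_db > max(intensity_db) + silence_db
  if (!any(sounding)) return(0)
  r <- rle(sounding)
  gap_frames <- round(min_pause_s / step)
  idx <- which(!r$values & r$lengths < gap_frames)
  # interior short gaps count as speech
  idx <- idx[idx > 1 & idx < length(r$values)]
  r$values[idx] <- TRUE
  sum(r$lengths[r$values]) * step
}

#' Temporal speech features
#'
#' Syllable count from intensity-peak nuclei detection, total and speaking
#' duration, speech rate (syllables per second of total duration),
#' articulation rate (syllables per second of speaking time), the
#' speaking-to-total ratio, and a pronunciation score defined as the
#' percentage of detected nuclei that fall in voiced frames.
#'
#' @param w a `waveform` (at least 1 s).
#' @param silence_db silence threshold relative to the intensity maximum.
#' @param min_dip_db minimum intensity dip between distinct nuclei.
#' @param min_pause_s minimum silent gap counted as a pause.
#' @return named numeric vector of 7 features.
#' @export
temporal_stats <- function(w, silence_db = -25, min_dip_db = 2,
                           min_pause_s = 0.3) {
  w <- resample_wave(w)
  x <- w$samples
  total <- wave_duration(w)
  stopifnot(total >= 1)
  int_db <- frame_intensity_db(x, w$rate)
  all_silent <- length(int_db) == 0 || max(x^2) < .EPS
  nuclei <- if (all_silent) integer(0)
            else detect_syllable_nuclei(int_db, silence_db = silence_db,
                                        min_dip_db = min_dip_db)
  speaking <- if (all_silent) 0
              else speaking_duration_s(int_db, silence_db = silence_db,
                                       min_pause_s = min_pause_s)
  n_syll <- length(nuclei)
  f0 <- if (all_silent) numeric(0) else frame_f0(x, w$rate)
  # nuclei are indexed on the 25 ms/10 ms intensity grid; the F0 grid uses
  # 40 ms/10 ms frames, so the same index addresses (nearly) the same time
  voiced_at <- function(i) {
    j <- min(max(i, 1L), length(f0))
    length(f0) > 0 && !is.na(f0[j])
  }
  pron <- if (n_syll == 0) NA_real_
          else 100 * mean(vapply(nuclei, voiced_at, logical(1)))
  c(syllable_count = n_syll,
    total_duration = total,
    speaking_duration = speaking,
    speech_rate = n_syll / total,
    articulation_rate = if (speaking > 0) n_syll / speaking else NA_real_,
    ratio_speaking = speaking / total,
    pronunciation_score = pron)
}

#' F0 statistics
#'
#' Mean, standard deviation, minimum, maximum and lower/upper quartiles of
#' the fundamental frequency over voiced frames (autocorrelation tracker,
#' 75-500 Hz search band).  All six are missing when no frame is voiced.
#'
#' @param w a `waveform`.
#' @return named numeric vector of 6 features, in Hz.
#' @export
f0_stats <- function(w) {
  w <- resample_wave(w)
  f0 <- frame_f0(w$samples, w$rate)
  f0 <- f0[!is.na(f0)]
  if (length(f0) == 0)
    return(c(f0_mean = NA_real_, f0_std = NA_real_, f0_min = NA_real_,
             f0_max = NA_real_, f0_q25 = NA_real_, f0_q75 = NA_real_))
  c(f0_mean = mean(f0),
    f0_std = if (length(f0) > 1) stats::sd(f0) else 0,
    f0_min = min(f0), f0_max = max(f0),
    f0_q25 = unname(stats::quantile(f0, 0.25)),
    f0_q75 = unname(stats::quantile(f0, 0.75)))
}

## --- MFCC -----------------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters = 26, nfft = 512, rate = 16000) {
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(rate / 2),
                 length.out = n_filters + 2)
  bins <- floor((nfft + 1) * mel_to_hz(mel_pts) / rate)
  fb <- matrix(0, n_filters, nfft %/% 2 + 1)
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; mid <- bins[m + 1]; hi <- bins[m + 2]
    if (mid > lo)
      for (k in lo:mid) fb[m, k + 1] <- (k - lo) / (mid - lo)
    if (hi > mid)
      for (k in mid:hi) fb[m, k + 1] <- (hi - k) / (hi - mid)
  }
  fb
}

# orthonormal DCT-II over the filterbank axis
dct2_ortho <- function(x) {
  n <- length(x)
  k <- seq_len(n) - 1
  out <- vapply(k, function(kk)
    sum(x * cos(pi * kk * (2 * (seq_len(n) - 1) + 1) / (2 * n))),
    numeric(1))
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  out * scale
}

#' Mel-frequency cepstral coefficient frames
#'
#' Standard MFCC pipeline: pre-emphasis (0.97), 25 ms Hamming-windowed
#' frames at a 10 ms step, 512-point power spectrum, a 26-filter mel
#' filterbank, log energies, and an orthonormal DCT-II of which the first
#' `n_coef` coefficients are kept (coefficient 0 is the static energy
#' term).
#'
#' @param w a `waveform`.
#' @param n_coef number of cepstral coefficients (default 14).
#' @param n_filters mel filters.
#' @param nfft FFT size.
#' @param preemph pre-emphasis coefficient.
#' @return matrix, frames x coefficients.
#' @export
mfcc_frames <- function(w, n_coef = 14, n_filters = 26, nfft = 512,
                        preemph = 0.97) {
  w <- resample_wave(w)
  x <- w$samples
  x <- c(x[1], x[-1] - preemph * x[-length(x)])
  fr <- frame_signal(x, w$rate)
  if (nrow(fr) == 0) return(matrix(numeric(0), 0, n_coef))
  L <- ncol(fr)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  fb <- mel_filterbank(n_filters, nfft, w$rate)
  out <- matrix(0, nrow(fr), n_coef)
  for (i in seq_len(nrow(fr))) {
    s <- c(fr[i, ] * win, rep(0, nfft - L))
    p <- Mod(stats::fft(s)[seq_len(nfft %/% 2 + 1)])^2 / nfft
    fe <- log(pmax(as.vector(fb %*% p), .EPS))
    out[i, ] <- dct2_ortho(fe)[seq_len(n_coef)]
  }
  out
}

#' MFCC summary features
#'
#' For each of 14 cepstral coefficients, statistics of the static stream
#' and of its velocity (first frame-to-frame difference) and acceleration
#' (difference of velocities): mean, variance, skewness and excess
#' kurtosis.  14 x 3 x 4 = 168 features.  Coefficient 0 is named `energy`,
#' the rest `mfcc1` ... `mfcc13`.
#'
#' @param w a `waveform` (at least 1 s; fewer than 3 frames leaves all
#'   features missing).
#' @return named numeric vector of 168 features.
#' @export
mfcc_stats <- function(w) {
  coef_names <- c("energy", paste0("mfcc", 1:13))
  stream_suffix <- c(static = "", velocity = "_velocity",
                     acceleration = "_accel")
  all_names <- as.vector(t(outer(
    as.vector(t(outer(coef_names, stream_suffix, paste0))),
    c("_mean", "_var", "_skewness", "_kurtosis"), paste0)))

  cc <- mfcc_frames(w)
  if (nrow(cc) < 3)
    return(stats::setNames(rep(NA_real_, length(all_names)), all_names))
  vel <- diff(cc)
  acc <- diff(vel)
  vals <- numeric(0)
  for (j in seq_len(ncol(cc)))
    for (s in list(cc[, j], vel[, j], acc[, j]))
      vals <- c(vals, moment_stats(s))
  stats::setNames(vals, all_names)
}

## --- spectral descriptors -------------------------------------------------

#' Spectral summary features
#'
#' Seven frame-level descriptors - RMS, spectral centroid, bandwidth,
#' flatness, zero-crossing rate (crossings per second), normalized
#' loudness (frame energy in dB of the peak-normalized signal) and
#' spectral flux - summarized by mean, max, min and standard deviation
#' (28 features).  Centroid and bandwidth are missing for an all-zero
#' signal.
#'
#' @param w a `waveform` (at least 1 s).
#' @return named numeric vector of 28 features.
#' @export
spectral_stats <- function(w) {
  w <- resample_wave(w)
  x <- w$samples
  stopifnot(wave_duration(w) >= 1)
  peak <- max(abs(x))
  xn <- if (peak > 0) x / peak else x
  fr <- frame_signal(x, w$rate)
  frn <- frame_signal(xn, w$rate)
  L <- ncol(fr)
  nfft <- 512
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  freqs <- (0:(nfft %/% 2)) * w$rate / nfft

  n_fr <- nrow(fr)
  rms <- cent <- bw <- flat <- zcr <- loud <- flux <- numeric(n_fr)
  prev_mag <- NULL
  for (i in seq_len(n_fr)) {
    f <- fr[i, ]
    rms[i] <- sqrt(mean(f^2))
    s <- sign(f); s[s == 0] <- 1
    zcr[i] <- sum(s[-1] != s[-L]) / (L / w$rate)
    loud[i] <- 10 * log10(mean(frn[i, ]^2) + .EPS)
    mag <- Mod(stats::fft(c(f * win, rep(0, nfft - L)))[seq_len(nfft %/% 2 + 1)])
    tot <- sum(mag)
    if (tot > .EPS) {
      cent[i] <- sum(freqs * mag) / tot
      bw[i] <- sqrt(sum(mag * (freqs - cent[i])^2) / tot)
    } else {
      cent[i] <- NA_real_; bw[i] <- NA_real_
    }
    pw <- mag^2
    flat[i] <- exp(mean(log(pw + .EPS))) / (mean(pw) + .EPS)
    flux[i] <- if (is.null(prev_mag)) 0 else sqrt(sum((mag - prev_mag)^2))
    prev_mag <- mag
  }

  stat4 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(c(mean = NA_real_, max = NA_real_, min = NA_real_,
               std = NA_real_))
    c(mean = mean(v), max = max(v), min = min(v),
      std = if (length(v) > 1) stats::sd(v) else 0)
  }
  desc <- list(rms = rms, centroid = cent, bandwidth = bw, flatness = flat,
               zcr = zcr, normalized_loudness = loud, flux = flux)
  out <- numeric(0)
  for (nm in names(desc)) {
    v <- stat4(desc[[nm]])
    names(v) <- paste0(nm, "_", c("mean", "max", "min", "std"))
    out <- c(out, v)
  }
  out
}

#' Paralinguistic registry names
#'
#' @return character vector of the 209 paralinguistic feature names
#'   (7 temporal + 6 F0 + 168 MFCC + 28 spectral).
#' @export
paralinguistic_feature_names <- function() {
  coef_names <- c("energy", paste0("mfcc", 1:13))
  stream_suffix <- c("", "_velocity", "_accel")
  mfcc_names <- as.vector(t(outer(
    as.vector(t(outer(coef_names, stream_suffix, paste0))),
    c("_mean", "_var", "_skewness", "_kurtosis"), paste0)))
  c("syllable_count", "total_duration", "speaking_duration", "speech_rate",
    "articulation_rate", "ratio_speaking", "pronunciation_score",
    "f0_mean", "f0_std", "f0_min", "f0_max", "f0_q25", "f0_q75",
    mfcc_names,
    as.vector(t(outer(c("rms", "centroid", "bandwidth", "flatness", "zcr",
                        "normalized_loudness", "flux"),
                      c("_mean", "_max", "_min", "_std"), paste0))))
}

#' Extract all paralinguistic features from a waveform
#'
#' @param w a `waveform`.
#' @return named numeric vector over the paralinguistic registry (209
#'   features).
#' @export
extract_audio_features <- function(w) {
  vals <- c(temporal_stats(w), f0_stats(w), mfcc_stats(w), spectral_stats(w))
  reg <- paralinguistic_feature_names()
  out <- vals[reg]
  names(out) <- reg
  out
}
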