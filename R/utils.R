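# Internal numerical helpers shared across modules.

#' Derive a deterministic child seed from a parent seed
#'
#' Child streams (per subject, per model, per iteration) are derived with a
#' Lehmer-style multiplicative congruential step so that a single top-level
#' integer seed reproduces the whole pipeline while the streams stay
#' decorrelated. Results stay within the positive 32-bit integer range.
#'
#' @param seed parent integer seed
#' @param index non-negative stream index
#' @return an integer seed
#' @keywords internal
child_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.double(seed) %% m + 1)
  for (k in seq_len(2L)) {
    x <- (x * 48271 + as.double(index) * 16807 + 12345) %% m
  }
  as.integer(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Hann window, mean-removed segments,
#' 50\% overlap). Used by the signal-quality gates and the spectral features.
#'
#' @param x numeric vector
#' @param fs sampling rate in Hz
#' @param seg_seconds segment length in seconds (default 4)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return list with `freq` (Hz) and `power` (one-sided PSD, arbitrary/Hz)
#' @keywords internal
welch_psd <- function(x, fs, seg_seconds = 4, overlap = 0.5) {
  n <- length(x)
  nper <- min(n, max(16L, as.integer(round(seg_seconds * fs))))
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  u <- sum(w^2)
  nfreq <- nper %/% 2L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    acc <- acc + (Mod(ft[seq_len(nfreq)])^2) / (u * fs)
  }
  p <- acc / length(starts)
  # fold to one-sided (DC bin excluded from doubling is immaterial for bands)
  p <- 2 * p
  freq <- (seq_len(nfreq) - 1L) * fs / nper
  list(freq = freq, power = p)
}

# Integrated band power from a PSD over [lo, hi) Hz.
band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq < hi
  if (!any(sel)) return(0)
  df <- if (length(psd$freq) > 1) psd$freq[2] - psd$freq[1] else 1
  sum(psd$power[sel]) * df
}

# Simple local-maximum peak picker with a minimum height and a refractory
# period; returns sample indices. Hand-rolled because the refractory logic is
# the whole point (the installed signal package does not provide one).
find_peaks <- function(x, min_height, refractory_samples) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) > refractory_samples)) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

# Block-mean decimation of a channels x samples matrix down to ~target_fs.
# The boxcar average doubles as a crude anti-alias filter; ample for the
# smooth sub-40 Hz content the detection and loop analyses operate on.
decimate_channels <- function(mat, fs, target_fs = 500) {
  k <- max(1L, as.integer(round(fs / target_fs)))
  if (k == 1L) return(list(mat = mat, fs = fs))
  m <- ncol(mat) %/% k
  dec <- vapply(seq_len(nrow(mat)), function(ch) {
    colMeans(matrix(mat[ch, seq_len(m * k)], nrow = k))
  }, numeric(m))
  list(mat = t(dec), fs = fs / k)
}

# Zero-phase Butterworth band-pass, falling back to a pass-through when the
# band covers the whole spectrum.
bandpass_filter <- function(x, fs, lo, hi, order = 4) {
  nyq <- fs / 2
  hi <- min(hi, 0.99 * nyq)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

highpass_filter <- function(x, fs, cutoff, order = 4) {
  nyq <- fs / 2
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

lowpass_filter <- function(x, fs, cutoff, order = 4) {
  nyq <- fs / 2
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# MD5 of an R object via canonical serialization (version 2, no ASCII), for
# the frozen-model manifest.
object_md5 <- function(object) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  serialize(object, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
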