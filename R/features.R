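#' Feature-extraction configuration
#'
#' @param repol_band band-pass (Hz) applied before the repolarization
#'   phase-space analysis
#' @param repol_points number of points each repolarization segment is
#'   resampled to before beat-to-beat comparison
#' @param spectral_bands list of `c(lo, hi)` Hz bands for OVG band-power
#'   fractions
#' @param resp_max_hz upper frequency bound of the respiration search band
#' @param resp_grid_hz uniform resampling rate for the per-beat amplitude
#'   series used as the respiration proxy
#' @return list of class `feature_config`
#' @export
feature_config <- function(repol_band = c(0.5, 40),
                           repol_points = 50L,
                           spectral_bands = list(
                             c(0.5, 5), c(5, 15), c(15, 40), c(40, 150)
                           ),
                           resp_max_hz = 0.5,
                           resp_grid_hz = 4) {
  structure(as.list(environment()), class = "feature_config")
}

#' Phase-space features: atrial vector and repolarization-loop dispersion
#'
#' The atrial depolarization vector of a beat is the mean phase-space point
#' over the beat's atrial window; reported features are the mean and SD of
#' its magnitude and its mean orientation (azimuth in the coronal-sagittal
#' plane, elevation towards the transverse axis). Repolarization-loop
#' dispersion is the mean over all beat pairs of the mean pointwise Euclidean
#' distance between repolarization segments, each band-pass filtered and
#' resampled to a common length.
#'
#' @param record an `acquisition_record`
#' @param cycles output of [segment_cycles()]
#' @param config a [feature_config()]
#' @return named list of `phase_space.*` scalars
#' @export
phase_space_features <- function(record, cycles, config = feature_config()) {
  fs <- record$ovg_rate
  traj <- phase_space_embed(record)

  vecs <- t(vapply(seq_len(nrow(cycles)), function(b) {
    lo <- max(1L, as.integer(cycles$atrial_onset[b] * fs) + 1L)
    hi <- min(nrow(traj), as.integer(cycles$atrial_offset[b] * fs))
    colMeans(traj[lo:hi, , drop = FALSE])
  }, numeric(3)))
  mags <- sqrt(rowSums(vecs^2))
  mv <- colMeans(vecs)

  # repolarization loop analysis at ~500 Hz where the 0.5-40 Hz band-pass is
  # well-conditioned; loop geometry is fully captured below 40 Hz
  dec <- decimate_channels(record$ovg, fs, 500)
  filt <- vapply(seq_len(nrow(dec$mat)), function(ch) {
    bandpass_filter(dec$mat[ch, ], dec$fs, config$repol_band[1], config$repol_band[2])
  }, numeric(ncol(dec$mat)))
  # segments are sampled at exact beat-relative times (block centres of the
  # decimated grid) so that beat-to-beat comparison is free of timing-grid
  # aliasing
  tgrid <- (seq_len(ncol(dec$mat)) - 0.5) / dec$fs
  segs <- lapply(seq_len(nrow(cycles)), function(b) {
    times <- seq(cycles$vrep_start[b], cycles$vrep_end[b],
                 length.out = config$repol_points)
    seg <- vapply(1:3, function(ch) {
      stats::approx(tgrid, filt[, ch], xout = times, rule = 2)$y
    }, numeric(config$repol_points))
    # per-channel centring: dispersion measures loop shape, not the slow
    # baseline each beat happens to ride on
    sweep(seg, 2, colMeans(seg))
  })
  disp <- repol_dispersion_pairs(segs)

  list(
    phase_space.atrial_vector_mag_mean = mean(mags),
    phase_space.atrial_vector_mag_sd = stats::sd(mags),
    phase_space.atrial_vector_azimuth = unname(atan2(mv[2], mv[1])),
    phase_space.atrial_vector_elevation = unname(atan2(mv[3], sqrt(mv[1]^2 + mv[2]^2))),
    phase_space.repol_dispersion = disp
  )
}

# Mean over all beat pairs of the mean pointwise distance between aligned
# repolarization segments.
repol_dispersion_pairs <- function(segs) {
  nb <- length(segs)
  if (nb < 2L) return(0)
  tot <- 0
  np <- 0L
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      d <- sqrt(rowSums((segs[[i]] - segs[[j]])^2))
      tot <- tot + mean(d)
      np <- np + 1L
    }
  }
  tot / np
}

#' PPG pulse-wave indicator features
#'
#' Collects the per-beat pulse-base values (nadir before the systolic
#' upstroke) and pulse amplitudes (systolic peak minus base) and reports
#' their summary statistics; the maximum of the pulse base is the leading
#' indicator.
#'
#' @inheritParams phase_space_features
#' @return named list of `ppg_indicator.*` scalars
#' @export
ppg_indicators <- function(record, cycles, config = feature_config()) {
  base <- cycles$ppg_base_value
  amp <- cycles$ppg_peak_value - cycles$ppg_base_value
  list(
    ppg_indicator.base_max = max(base),
    ppg_indicator.base_mean = mean(base),
    ppg_indicator.base_sd = stats::sd(base),
    ppg_indicator.amp_mean = mean(amp),
    ppg_indicator.amp_sd = stats::sd(amp)
  )
}

#' Spectral, synchronization and respiration features
#'
#' OVG band-power fractions over the configured bands (channel-averaged Welch
#' PSD); per-beat OVG-onset to PPG-foot delay statistics; and a respiration
#' proxy — the dominant frequency (below `resp_max_hz`) of the beat-to-beat
#' pulse-amplitude modulation series, resampled onto a uniform grid.
#'
#' @inheritParams phase_space_features
#' @return named list of `ovg_spectral.*`, `sync.*`, `respiration.*` scalars
#' @export
spectral_and_sync_features <- function(record, cycles, config = feature_config()) {
  psds <- lapply(1:3, function(ch) welch_psd(record$ovg[ch, ], record$ovg_rate))
  total <- vapply(psds, function(p) band_power(p, 0.5, 150), numeric(1))
  fractions <- vapply(config$spectral_bands, function(b) {
    bp <- vapply(psds, function(p) band_power(p, b[1], b[2]), numeric(1))
    mean(bp / pmax(total, .Machine$double.xmin))
  }, numeric(1))
  names(fractions) <- vapply(config$spectral_bands, function(b) {
    sprintf("ovg_spectral.bp_%s_%s", gsub("\\.", "p", b[1]), gsub("\\.", "p", b[2]))
  }, character(1))

  delay <- (cycles$ppg_base_time - cycles$onset) * 1000

  amp <- cycles$ppg_peak_value - cycles$ppg_base_value
  tt <- cycles$onset
  resp_freq <- NA_real_
  resp_depth <- NA_real_
  if (nrow(cycles) >= 8L && diff(range(tt)) > 8) {
    grid <- seq(min(tt), max(tt), by = 1 / config$resp_grid_hz)
    series <- stats::approx(tt, amp, xout = grid)$y
    series <- series - mean(series)
    n <- length(series)
    ft <- stats::fft(series)
    freq <- (seq_len(n %/% 2) - 1) / (n / config$resp_grid_hz)
    pow <- Mod(ft[seq_len(n %/% 2)])^2
    sel <- freq > 0.05 & freq <= config$resp_max_hz
    if (any(sel)) {
      k <- which(sel)[which.max(pow[sel])]
      resp_freq <- freq[k]
      resp_depth <- 2 * sqrt(pow[k]) / n / max(mean(amp), .Machine$double.eps)
    }
  }

  c(
    as.list(fractions),
    list(
      sync.delay_mean = mean(delay),
      sync.delay_sd = stats::sd(delay),
      respiration.dominant_freq = resp_freq,
      respiration.modulation_depth = resp_depth
    )
  )
}

#' Time-domain features
#'
#' Heart-rate statistics from the detected beat intervals, atrial
#' depolarization duration statistics (including the variation exemplar), and
#' the RMS residual of each beat's magnitude waveform against the
#' subject-specific median-beat template.
#'
#' @inheritParams phase_space_features
#' @return named list of `time_domain.*` scalars
#' @export
time_domain_features <- function(record, cycles, config = feature_config()) {
  fs <- record$ovg_rate
  ibi <- diff(cycles$onset)
  mag <- sqrt(colSums(record$ovg^2))
  L <- 120L
  beats <- t(vapply(seq_len(nrow(cycles)), function(b) {
    lo <- max(1L, as.integer(cycles$onset[b] * fs) + 1L)
    hi <- min(length(mag), as.integer((cycles$onset[b] + 0.55) * fs))
    stats::approx(seq(lo, hi), mag[lo:hi], n = L)$y
  }, numeric(L)))
  template <- apply(beats, 2, stats::median)
  resid <- sqrt(rowMeans(sweep(beats, 2, template)^2))
  list(
    time_domain.hr_mean = 60 / mean(ibi),
    time_domain.hr_sd = stats::sd(60 / ibi),
    time_domain.atrial_duration_mean = mean(cycles$atrial_duration_ms),
    time_domain.atrial_duration_sd = atrial_duration_variation(cycles),
    time_domain.template_residual_rms = mean(resid)
  )
}

#' Extract the full feature row for one acquisition
#'
#' Segments the record (unless annotations are supplied) and concatenates the
#' time-domain, phase-space, PPG-indicator, spectral, synchronization and
#' respiration families into a single named row. Deterministic given the
#' record.
#'
#' @param record an `acquisition_record`
#' @param cycles optional precomputed [segment_cycles()] output
#' @param config a [feature_config()]
#' @param seg_config a [segment_config()]
#' @return one-row data.frame with `subject_id` plus family-prefixed feature
#'   columns
#' @export
#' @examples
#' rec <- generate_signals(generate_cohort(1, seed = 5), signal_config(duration = 15), seed = 5)
#' extract_features(rec)[, 1:4]
extract_features <- function(record, cycles = NULL, config = feature_config(),
                             seg_config = segment_config()) {
  if (is.null(cycles)) cycles <- segment_cycles(record, seg_config)
  feats <- c(
    time_domain_features(record, cycles, config),
    phase_space_features(record, cycles, config),
    ppg_indicators(record, cycles, config),
    spectral_and_sync_features(record, cycles, config)
  )
  cbind(data.frame(subject_id = record$subject_id, stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Extract features for a list of acquisitions
#'
#' @param records list of `acquisition_record`s
#' @param ... passed to [extract_features()]
#' @return data.frame with one row per record (the feature table)
#' @export
extract_features_cohort <- function(records, ...) {
  do.call(rbind, lapply(records, extract_features, ...))
}
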