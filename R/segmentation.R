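#' Cycle-segmentation configuration
#'
#' Timing assumptions used to place per-beat analysis windows around each
#' detected ventricular depolarization. Windows are half-open `[start, end)`
#' in seconds from record start.
#'
#' @param band band-pass applied to the OVG magnitude before peak picking (Hz)
#' @param refractory_s minimum separation between detected beats (seconds)
#' @param peak_fraction detection threshold as a fraction of the magnitude
#'   signal's maximum
#' @param vdep_offset_s assumed onset-to-depolarization-peak interval
#' @param atrial_search_s atrial wave search window length after cycle onset
#' @param vdep_window_s depolarization window relative to onset, `c(start, end)`
#' @param vrep_window_s repolarization window relative to onset, `c(start, end)`
#' @param ppg_delay_s assumed onset-to-pulse-foot delay used to centre the
#'   PPG base search
#' @param min_beats minimum number of detected beats below which segmentation
#'   aborts
#' @return list of class `segment_config`
#' @export
segment_config <- function(band = c(0.5, 40),
                           refractory_s = 0.25,
                           peak_fraction = 0.5,
                           vdep_offset_s = 0.19,
                           atrial_search_s = 0.15,
                           vdep_window_s = c(0.15, 0.26),
                           vrep_window_s = c(0.26, 0.50),
                           ppg_delay_s = 0.20,
                           min_beats = 10L) {
  structure(as.list(environment()), class = "segment_config")
}

#' Segment an acquisition into cardiac cycles
#'
#' Detects beats on the band-passed 3-channel OVG magnitude with a refractory
#' peak picker, then annotates each beat: cycle onset, atrial depolarization
#' on/offset (threshold-crossing width of the atrial wave), depolarization
#' and repolarization windows, and the PPG pulse base (per-beat nadir
#' immediately preceding the systolic upstroke, taken on the infrared
#' channel).
#'
#' @param record an `acquisition_record` (should have passed QC)
#' @param config a [segment_config()]
#' @return data.frame with one row per beat: `beat_index`, `onset`,
#'   `atrial_onset`, `atrial_offset`, `atrial_duration_ms`, `vdep_start`,
#'   `vdep_end`, `vrep_start`, `vrep_end`, `ppg_base_time`, `ppg_base_value`,
#'   `ppg_peak_value` (times in seconds)
#' @export
#' @examples
#' rec <- generate_signals(generate_cohort(1, seed = 4), signal_config(duration = 15), seed = 4)
#' head(segment_cycles(rec))
segment_cycles <- function(record, config = segment_config()) {
  stopifnot(inherits(record, "acquisition_record"))
  fs <- record$ovg_rate
  # detection runs at ~500 Hz: the 0.5-40 Hz Butterworth is numerically
  # well-conditioned there, and beat timing needs no 8 kHz resolution
  dec <- decimate_channels(record$ovg, fs, 500)
  filt <- vapply(seq_len(nrow(dec$mat)), function(ch) {
    bandpass_filter(dec$mat[ch, ], dec$fs, config$band[1], config$band[2])
  }, numeric(ncol(dec$mat)))
  mag <- sqrt(rowSums(filt^2))
  peaks <- find_peaks(mag, config$peak_fraction * max(mag),
                      as.integer(config$refractory_s * dec$fs))
  if (length(peaks) < config$min_beats) {
    stop(structure(
      class = c("no_cycles_detected", "error", "condition"),
      list(message = sprintf("only %d beats detected (need >= %d)",
                             length(peaks), config$min_beats),
           call = NULL)
    ))
  }
  # refine each coarse peak on the full-rate raw magnitude (+/- 10 ms) so
  # beat timing carries 8 kHz rather than 500 Hz resolution
  mag_full <- sqrt(colSums(record$ovg^2))
  peak_times <- vapply(peaks, function(p) {
    centre <- p / dec$fs
    lo <- max(1L, as.integer((centre - 0.01) * fs))
    hi <- min(length(mag_full), as.integer((centre + 0.01) * fs))
    (lo + which.max(mag_full[lo:hi]) - 1L) / fs
  }, numeric(1))
  onsets <- peak_times - config$vdep_offset_s
  keep <- onsets > 0 & onsets + config$vrep_window_s[2] < record$duration
  onsets <- onsets[keep]

  # atrial duration: threshold-crossing width of the atrial bump, measured on
  # the raw (unfiltered) magnitude so the band-pass baseline shift cannot
  # bias the crossing points; the exp(-4.5) level maps a Gaussian bump's
  # crossing width to its nominal 6-sigma duration
  mag_raw <- mag_full
  level <- exp(-4.5)
  ann <- lapply(seq_along(onsets), function(b) {
    on <- onsets[b]
    lo <- max(1L, as.integer(on * fs) + 1L)
    hi <- min(length(mag_raw), as.integer((on + config$atrial_search_s) * fs))
    seg <- mag_raw[lo:hi]
    pk <- which.max(seg)
    thr <- level * seg[pk]
    left <- pk
    while (left > 1L && seg[left - 1L] > thr) left <- left - 1L
    right <- pk
    while (right < length(seg) && seg[right + 1L] > thr) right <- right + 1L
    a_on <- (lo + left - 2L) / fs
    a_off <- (lo + right - 1L) / fs
    c(onset = on, atrial_onset = a_on, atrial_offset = a_off)
  })
  ann <- as.data.frame(do.call(rbind, ann))

  # PPG base: nadir just before the systolic upstroke (infrared channel)
  pfs <- record$ppg_rate
  ir <- record$ppg[nrow(record$ppg), ]
  ppg_base <- t(vapply(ann$onset, function(on) {
    centre <- on + config$ppg_delay_s
    lo <- max(1L, as.integer((centre - 0.10) * pfs) + 1L)
    hi <- min(length(ir), as.integer((centre + 0.05) * pfs))
    if (hi <= lo) return(c(NA_real_, NA_real_, NA_real_))
    seg <- ir[lo:hi]
    # foot = last point at the nadir before the upstroke (ties resolve late)
    eps <- 0.005 * (max(seg) - min(seg)) + 1e-12
    i <- max(which(seg <= min(seg) + eps))
    phi <- min(length(ir), as.integer((centre + 0.40) * pfs))
    pk <- max(ir[lo:phi])
    c((lo + i - 2L) / pfs, min(seg), pk)
  }, numeric(3)))

  out <- data.frame(
    beat_index = seq_len(nrow(ann)),
    onset = ann$onset,
    atrial_onset = ann$atrial_onset,
    atrial_offset = ann$atrial_offset,
    atrial_duration_ms = (ann$atrial_offset - ann$atrial_onset) * 1000,
    vdep_start = ann$onset + config$vdep_window_s[1],
    vdep_end = ann$onset + config$vdep_window_s[2],
    vrep_start = ann$onset + config$vrep_window_s[1],
    vrep_end = ann$onset + config$vrep_window_s[2],
    ppg_base_time = ppg_base[, 1],
    ppg_base_value = ppg_base[, 2],
    ppg_peak_value = ppg_base[, 3]
  )
  stats::na.omit(out)
}

#' Variation of the atrial depolarization duration
#'
#' Sample standard deviation (n-1 denominator) of the per-beat atrial
#' depolarization durations — the time-domain exemplar feature.
#'
#' @param cycles output of [segment_cycles()], or a numeric vector of
#'   durations in ms
#' @return standard deviation in ms
#' @export
atrial_duration_variation <- function(cycles) {
  d <- if (is.data.frame(cycles)) cycles$atrial_duration_ms else as.numeric(cycles)
  if (length(d) < 2L) stopf("need at least 2 cycles to estimate variation")
  stats::sd(d)
}

#' Embed an OVG record in three-dimensional phase space
#'
#' Each time sample's three channel amplitudes form one coordinate; the
#' trajectory preserves time order and applies no smoothing.
#'
#' @param record an `acquisition_record`, or a 3 x N numeric matrix
#' @return N x 3 matrix (columns: coronal, sagittal, transverse; microvolts)
#' @export
phase_space_embed <- function(record) {
  m <- if (inherits(record, "acquisition_record")) record$ovg else record
  if (!is.matrix(m) || nrow(m) != 3L) {
    stopf("need 3 equal-length channels for phase-space embedding")
  }
  out <- t(m)
  colnames(out) <- c("coronal", "sagittal", "transverse")
  out
}
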