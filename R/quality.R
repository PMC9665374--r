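#' Quality-gate configuration
#'
#' Thresholds and frequency bands for the three signal-acceptance gates
#' applied before feature extraction: powerline SNR, high-frequency SNR, and
#' PPG sensor saturation. The SNR thresholds default to the acceptance values
#' 57 dB (powerline) and 19 dB (high frequency); the physiological signal
#' band is 0.5--40 Hz, the powerline band 60 +/- 0.5 Hz, and the
#' high-frequency band everything above 150 Hz. Saturation is a fraction, not
#' an SNR: the gate passes when at most `saturation_tolerance` of PPG samples
#' sit at the sensor ceiling.
#'
#' @param powerline_threshold_db pass threshold for powerline SNR (dB)
#' @param highfreq_threshold_db pass threshold for high-frequency SNR (dB)
#' @param saturation_tolerance maximum acceptable saturated fraction
#' @param signal_band signal band in Hz, `c(lo, hi)`
#' @param powerline_band powerline band in Hz
#' @param highfreq_cutoff lower edge of the high-frequency noise band (Hz)
#' @param channel_aggregate `"mean"` (default) or `"worst"` across the three
#'   OVG channels
#' @param ppg_ceiling PPG saturation ceiling; `NULL` takes it from the
#'   record's generation config
#' @return list of class `quality_config`
#' @export
quality_config <- function(powerline_threshold_db = 57,
                           highfreq_threshold_db = 19,
                           saturation_tolerance = 0.05,
                           signal_band = c(0.5, 40),
                           powerline_band = c(59.5, 60.5),
                           highfreq_cutoff = 150,
                           channel_aggregate = c("mean", "worst"),
                           ppg_ceiling = NULL) {
  channel_aggregate <- match.arg(channel_aggregate)
  structure(as.list(environment()), class = "quality_config")
}

snr_over_band <- function(record, noise_lo, noise_hi, config) {
  if (all(record$ovg == 0)) stopf("all-zero OVG signal: SNR undefined")
  per_ch <- vapply(1:3, function(ch) {
    psd <- welch_psd(record$ovg[ch, ], record$ovg_rate)
    sig <- band_power(psd, config$signal_band[1], config$signal_band[2])
    noi <- band_power(psd, noise_lo, noise_hi)
    if (noi <= 0) noi <- .Machine$double.xmin
    10 * log10(sig / noi)
  }, numeric(1))
  if (config$channel_aggregate == "worst") min(per_ch) else mean(per_ch)
}

#' Powerline signal-to-noise ratio
#'
#' Ratio (dB) of physiological-band power (0.5--40 Hz) to 60 Hz-band power
#' (60 +/- 0.5 Hz), estimated by Welch periodogram (4 s Hann segments, 50\%
#' overlap) and aggregated over the three OVG channels. Larger is cleaner.
#'
#' @param record an `acquisition_record`
#' @param config a [quality_config()]
#' @return SNR in dB
#' @export
powerline_snr <- function(record, config = quality_config()) {
  stopifnot(inherits(record, "acquisition_record"))
  if (record$duration < 10) stopf("need at least 10 s of signal")
  snr_over_band(record, config$powerline_band[1], config$powerline_band[2], config)
}

#' High-frequency signal-to-noise ratio
#'
#' As [powerline_snr()] with the noise band running from `highfreq_cutoff`
#' (default 150 Hz) to the Nyquist frequency.
#'
#' @inheritParams powerline_snr
#' @return SNR in dB
#' @export
highfreq_snr <- function(record, config = quality_config()) {
  stopifnot(inherits(record, "acquisition_record"))
  if (record$duration < 10) stopf("need at least 10 s of signal")
  snr_over_band(record, config$highfreq_cutoff, record$ovg_rate / 2, config)
}

#' PPG saturation fraction
#'
#' Fraction of PPG samples at or above the sensor ceiling, across both
#' optical channels. The gate passes when the fraction does not exceed the
#' configured tolerance.
#'
#' @inheritParams powerline_snr
#' @return list with `fraction` and `pass`
#' @export
ppg_saturation <- function(record, config = quality_config()) {
  stopifnot(inherits(record, "acquisition_record"))
  if (!length(record$ppg)) stopf("empty PPG signal")
  ceiling_val <- config$ppg_ceiling %||% record$config$ppg_max %||% max(record$ppg)
  frac <- mean(record$ppg >= ceiling_val)
  list(fraction = frac, pass = frac <= config$saturation_tolerance)
}

#' Assess signal quality for one acquisition
#'
#' Runs the three acceptance gates and combines them into an overall verdict
#' (the conjunction of the three pass flags).
#'
#' @inheritParams powerline_snr
#' @return one-row data.frame: `subject_id`, `powerline_snr`, `highfreq_snr`,
#'   `saturation_fraction`, `pass_powerline`, `pass_highfreq`,
#'   `pass_saturation`, `overall_pass`
#' @export
#' @examples
#' rec <- generate_signals(generate_cohort(1, seed = 3), signal_config(duration = 12), seed = 3)
#' assess_quality(rec)
assess_quality <- function(record, config = quality_config()) {
  pl <- powerline_snr(record, config)
  hf <- highfreq_snr(record, config)
  sat <- ppg_saturation(record, config)
  data.frame(
    subject_id = record$subject_id,
    powerline_snr = pl,
    highfreq_snr = hf,
    saturation_fraction = sat$fraction,
    pass_powerline = pl >= config$powerline_threshold_db,
    pass_highfreq = hf >= config$highfreq_threshold_db,
    pass_saturation = sat$pass,
    overall_pass = pl >= config$powerline_threshold_db &
      hf >= config$highfreq_threshold_db & sat$pass,
    stringsAsFactors = FALSE
  )
}
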