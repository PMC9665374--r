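#' Signal-generation configuration
#'
#' Parameters of the per-subject electro-mechanical signal model. Each cardiac
#' cycle is a sum of three Gaussian-bump wave templates — atrial
#' depolarization, ventricular depolarization, and ventricular repolarization
#' — projected onto the three orthogonal voltage-gradient (OVG) planes with
#' distinct fixed orientations, plus a PPG pulse train whose foot (pulse base)
#' trails each cardiac cycle by a perfusion delay. Three latent effects scale
#' monotonically with LVEDP through a clamped linear link
#' `e = clamp((lvedp - 12) / 13, 0, 1)`:
#' beat-to-beat jitter of the atrial depolarization duration, the PPG
#' pulse-base level, and the beat-to-beat dispersion of the repolarization
#' loop.
#'
#' @param duration acquisition length in seconds (protocol default 210 s,
#'   i.e. 3.5 minutes)
#' @param ovg_rate OVG sampling rate in Hz (8000)
#' @param ppg_rate PPG sampling rate in Hz (500)
#' @param ovg_resolution OVG amplitude quantum in microvolts (0.024)
#' @param heart_rate_bpm mean heart rate (beats per minute)
#' @param heart_rate_sd_bpm beat-to-beat heart-rate standard deviation
#' @param atrial_duration_ms mean atrial depolarization duration
#' @param atrial_jitter_sd_ms pair `c(base, slope)`: jitter SD in ms is
#'   `base + slope * e`
#' @param pulse_base pair `c(base, slope)` for the PPG pulse-base level
#'   (arbitrary optical units)
#' @param repol_dispersion pair `c(base, slope)`: SD (microvolts) of the
#'   per-beat perturbation of the repolarization-loop amplitude vector
#' @param pr_interval_s onset-to-ventricular-depolarization interval
#' @param ppg_delay_s cycle-onset-to-PPG-foot perfusion delay
#' @param ppg_amplitude systolic pulse amplitude (optical units)
#' @param ppg_max PPG sensor ceiling (optical units)
#' @param resp_rate_hz respiration rate used to amplitude-modulate the pulse
#' @param resp_depth fractional amplitude-modulation depth
#' @param ovg_noise_sd additive broadband OVG noise SD in microvolts
#'   (0 = clean; clinical noise is injected explicitly via [inject_noise()])
#' @param ppg_noise_sd additive PPG noise SD in optical units
#' @return a list of class `signal_config`
#' @export
signal_config <- function(duration = 210,
                          ovg_rate = 8000,
                          ppg_rate = 500,
                          ovg_resolution = 0.024,
                          heart_rate_bpm = 70,
                          heart_rate_sd_bpm = 2,
                          atrial_duration_ms = 100,
                          atrial_jitter_sd_ms = c(base = 2, slope = 8),
                          pulse_base = c(base = 1000, slope = 80),
                          repol_dispersion = c(base = 2, slope = 30),
                          pr_interval_s = 0.16,
                          ppg_delay_s = 0.20,
                          ppg_amplitude = 300,
                          ppg_max = 2000,
                          resp_rate_hz = 0.25,
                          resp_depth = 0.15,
                          ovg_noise_sd = 0,
                          ppg_noise_sd = 0) {
  if (duration <= 0) stopf("duration must be positive")
  if (heart_rate_bpm <= 0) stopf("heart_rate_bpm must be positive")
  structure(as.list(environment()), class = "signal_config")
}

# LVEDP -> latent effect in [0, 1]: linear ramp between the normal (12 mmHg)
# and elevated (25 mmHg) cut-points, clamped outside.
lvedp_effect <- function(lvedp) pmin(pmax((lvedp - 12) / 13, 0), 1)

# Fixed unit orientations of the three wave loops in OVG space (coronal,
# sagittal, transverse components).
wave_orientations <- function() {
  norm1 <- function(v) v / sqrt(sum(v^2))
  list(
    atrial = norm1(c(0.60, 0.60, 0.50)),
    vdep   = norm1(c(0.80, -0.50, 0.35)),
    vrep   = norm1(c(0.40, 0.70, -0.60))
  )
}

#' Generate one subject's OVG and PPG acquisition
#'
#' Simulates a 3-channel OVG record at `ovg_rate` and a 2-channel (red,
#' infrared) PPG record at `ppg_rate` for the configured duration, with the
#' three LVEDP-linked effects applied and full ground truth recorded. OVG
#' samples are quantized to the configured amplitude resolution.
#'
#' @param subject one row of a cohort data.frame (needs `lvedp`; `subject_id`
#'   used for labelling)
#' @param config a [signal_config()]
#' @param seed integer seed
#' @return an object of class `acquisition_record`: list with `ovg` (3 x N
#'   matrix, microvolts), `ppg` (2 x M matrix, optical units), `ovg_rate`,
#'   `ppg_rate`, `duration`, `subject_id`, and `truth` (beat onsets in
#'   seconds, per-beat atrial durations in ms, per-beat pulse-base values,
#'   injected-noise log, latent `effect_params`)
#' @export
#' @examples
#' subj <- generate_cohort(1, seed = 2)
#' rec <- generate_signals(subj, signal_config(duration = 12), seed = 2)
#' dim(rec$ovg)
generate_signals <- function(subject, config = signal_config(), seed = 1L) {
  if (!inherits(config, "signal_config")) stopf("config must be a signal_config")
  if (config$duration <= 0 || config$heart_rate_bpm <= 0) {
    stopf("non-positive duration or heart rate")
  }
  lvedp <- as.numeric(subject$lvedp[1])
  eff <- lvedp_effect(lvedp)
  set.seed(child_seed(seed, 1L))

  atr_sd_ms <- config$atrial_jitter_sd_ms[["base"]] +
    config$atrial_jitter_sd_ms[["slope"]] * eff
  base_level <- config$pulse_base[["base"]] + config$pulse_base[["slope"]] * eff
  rep_disp <- config$repol_dispersion[["base"]] +
    config$repol_dispersion[["slope"]] * eff

  dur <- config$duration
  n_ovg <- as.integer(round(config$ovg_rate * dur))
  n_ppg <- as.integer(round(config$ppg_rate * dur))
  t_ovg <- (seq_len(n_ovg) - 1L) / config$ovg_rate
  t_ppg <- (seq_len(n_ppg) - 1L) / config$ppg_rate

  # beat onsets with beat-to-beat period jitter
  mean_period <- 60 / config$heart_rate_bpm
  sd_period <- mean_period * config$heart_rate_sd_bpm / config$heart_rate_bpm
  onsets <- numeric(0)
  t0 <- 0.1
  while (t0 < dur - 0.6) {
    onsets <- c(onsets, t0)
    t0 <- t0 + max(0.3, stats::rnorm(1, mean_period, sd_period))
  }
  nb <- length(onsets)
  if (nb < 1L) stopf("duration too short for a single cardiac cycle")

  atr_dur_ms <- stats::rnorm(nb, config$atrial_duration_ms, atr_sd_ms)
  atr_dur_ms <- pmax(40, atr_dur_ms)
  base_vals <- base_level + stats::rnorm(nb, 0, 1)

  ori <- wave_orientations()
  amp <- list(atrial = 100, vdep = 1000, vrep = 300) # microvolts
  ovg <- matrix(0, nrow = 3L, ncol = n_ovg)
  for (b in seq_len(nb)) {
    on <- onsets[b]
    d <- atr_dur_ms[b] / 1000
    # atrial bump spans [on, on + d]; sigma = d/6 keeps ~99.7% inside
    add_bump <- function(center, sigma, vec, scale) {
      lo <- max(1L, as.integer(floor((center - 5 * sigma) * config$ovg_rate)))
      hi <- min(n_ovg, as.integer(ceiling((center + 5 * sigma) * config$ovg_rate)))
      if (hi <= lo) return(invisible(NULL))
      idx <- lo:hi
      g <- exp(-0.5 * ((t_ovg[idx] - center) / sigma)^2)
      for (ch in 1:3) ovg[ch, idx] <<- ovg[ch, idx] + scale * vec[ch] * g
      invisible(NULL)
    }
    add_bump(on + d / 2, d / 6, ori$atrial, amp$atrial)
    add_bump(on + config$pr_interval_s + 0.03, 0.012, ori$vdep, amp$vdep)
    # repolarization loop with per-beat orientation perturbation (dispersion)
    pert <- stats::rnorm(3, 0, rep_disp)
    vrep_vec <- ori$vrep + pert / amp$vrep
    add_bump(on + 0.35, 0.05, vrep_vec, amp$vrep)
  }
  if (config$ovg_noise_sd > 0) {
    ovg <- ovg + matrix(stats::rnorm(3L * n_ovg, 0, config$ovg_noise_sd), nrow = 3L)
  }
  ovg <- round(ovg / config$ovg_resolution) * config$ovg_resolution

  # PPG: per-beat baseline step at the pulse foot + raised-cosine systolic
  # pulse, amplitude-modulated by respiration; infrared = channel 2 at full
  # amplitude, red = channel 1 at 85%.
  # Baseline segments are attached to the *upcoming* beat so that the nadir
  # immediately before each systolic upstroke equals that beat's pulse-base
  # truth value; the raised-cosine pulse rides on top and returns to the base.
  ppg1 <- rep(base_vals[1L], n_ppg)
  resp_gain <- 1 + config$resp_depth * sin(2 * pi * config$resp_rate_hz * t_ppg)
  pulse_width <- 0.30
  prev_end <- 1L
  for (b in seq_len(nb)) {
    foot <- onsets[b] + config$ppg_delay_s
    lo <- as.integer(floor(foot * config$ppg_rate)) + 1L
    hi <- min(n_ppg, as.integer(ceiling((foot + pulse_width) * config$ppg_rate)))
    if (prev_end <= n_ppg) {
      seg_end <- if (b < nb) min(n_ppg, hi) else n_ppg
      if (seg_end >= prev_end) ppg1[prev_end:seg_end] <- base_vals[b]
    }
    if (lo <= n_ppg && hi >= lo) {
      idx <- lo:hi
      ph <- (t_ppg[idx] - foot) / pulse_width
      pulse <- 0.5 * (1 - cos(2 * pi * pmin(pmax(ph, 0), 1)))
      ppg1[idx] <- ppg1[idx] + config$ppg_amplitude * resp_gain[idx] * pulse
    }
    prev_end <- min(hi + 1L, n_ppg + 1L)
  }
  if (config$ppg_noise_sd > 0) ppg1 <- ppg1 + stats::rnorm(n_ppg, 0, config$ppg_noise_sd)
  ppg <- rbind(red = 0.85 * ppg1, infrared = ppg1)
  ppg <- pmin(ppg, config$ppg_max)

  structure(list(
    subject_id = as.character(subject$subject_id[1] %||% "anon"),
    ovg = ovg,
    ppg = ppg,
    ovg_rate = config$ovg_rate,
    ppg_rate = config$ppg_rate,
    duration = dur,
    config = config,
    truth = list(
      beat_onsets = onsets,
      atrial_durations = atr_dur_ms,
      pulse_base_values = base_vals,
      injected_noise = list(),
      effect_params = c(
        atrial_jitter_sd_ms = atr_sd_ms,
        pulse_base = base_level,
        repol_dispersion = rep_disp
      )
    )
  ), class = "acquisition_record")
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf(
    "<acquisition_record %s: OVG 3 x %d @ %g Hz, PPG 2 x %d @ %g Hz, %gs, %d beats>\n",
    x$subject_id, ncol(x$ovg), x$ovg_rate, ncol(x$ppg), x$ppg_rate,
    x$duration, length(x$truth$beat_onsets)
  ))
  invisible(x)
}

#' Inject clinical-environment noise into an acquisition
#'
#' Adds one of the three noise modes the quality gates screen for:
#' \describe{
#'   \item{powerline60}{a 60 Hz sinusoid on every OVG channel with RMS equal
#'     to `level` times the channel RMS (so the 60 Hz band-power to
#'     signal-power ratio is `level^2`)}
#'   \item{highfreq}{band-limited noise above `cutoff_hz` (default 150 Hz) on
#'     every OVG channel, RMS-scaled to `level` times the channel RMS}
#'   \item{ppg_saturation}{clips a random fraction `level` of PPG samples to
#'     the configured sensor ceiling}
#' }
#' `level = 0` returns the record unchanged. The injection is logged in
#' `truth$injected_noise`.
#'
#' @param record an `acquisition_record`
#' @param kind one of `"powerline60"`, `"highfreq"`, `"ppg_saturation"`
#' @param level non-negative noise level (RMS ratio, or saturated fraction)
#' @param cutoff_hz high-frequency noise cutoff (Hz)
#' @param seed integer seed for the stochastic modes
#' @return the modified `acquisition_record`
#' @export
inject_noise <- function(record, kind, level, cutoff_hz = 150, seed = 1L) {
  stopifnot(inherits(record, "acquisition_record"))
  if (level < 0) stopf("level must be >= 0")
  kind <- match.arg(kind, c("powerline60", "highfreq", "ppg_saturation"))
  if (level == 0) return(record)
  set.seed(child_seed(seed, 7L))
  if (kind == "powerline60") {
    n <- ncol(record$ovg)
    tt <- (seq_len(n) - 1L) / record$ovg_rate
    phase <- stats::runif(1, 0, 2 * pi)
    s <- sin(2 * pi * 60 * tt + phase)
    for (ch in 1:3) {
      rms <- sqrt(mean(record$ovg[ch, ]^2))
      record$ovg[ch, ] <- record$ovg[ch, ] + level * rms * sqrt(2) * s
    }
    q <- record$config$ovg_resolution %||% 0.024
    record$ovg <- round(record$ovg / q) * q
  } else if (kind == "highfreq") {
    n <- ncol(record$ovg)
    for (ch in 1:3) {
      w <- highpass_filter(stats::rnorm(n), record$ovg_rate, cutoff_hz)
      w <- w / sqrt(mean(w^2))
      rms <- sqrt(mean(record$ovg[ch, ]^2))
      record$ovg[ch, ] <- record$ovg[ch, ] + level * rms * w
    }
    q <- record$config$ovg_resolution %||% 0.024
    record$ovg <- round(record$ovg / q) * q
  } else {
    m <- ncol(record$ppg)
    k <- as.integer(ceiling(level * m))
    idx <- sample.int(m, min(k, m))
    ceiling_val <- record$config$ppg_max %||% max(record$ppg)
    record$ppg[, idx] <- ceiling_val
  }
  record$truth$injected_noise <- c(
    record$truth$injected_noise,
    list(list(kind = kind, level = level))
  )
  record
}

#' Write / read an acquisition as plain-text files
#'
#' Stores the OVG and PPG channel matrices as headerless CSV alongside a JSON
#' sidecar carrying sampling metadata and the ground truth. Intended for small
#' desk-scale records.
#'
#' @param record an `acquisition_record`
#' @param dir directory (created if needed); files are
#'   `<subject_id>_ovg.csv`, `<subject_id>_ppg.csv`, `<subject_id>_meta.json`
#' @return `write_acquisition()` the directory invisibly;
#'   `read_acquisition()` the reconstructed record
#' @export
write_acquisition <- function(record, dir) {
  stopifnot(inherits(record, "acquisition_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$subject_id
  utils::write.table(record$ovg, file.path(dir, paste0(id, "_ovg.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(record$ppg, file.path(dir, paste0(id, "_ppg.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(
    subject_id = id, ovg_rate = record$ovg_rate, ppg_rate = record$ppg_rate,
    duration = record$duration, truth = record$truth
  )
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_acquisition
#' @param subject_id subject identifier to read back
#' @export
read_acquisition <- function(dir, subject_id) {
  meta_path <- file.path(dir, paste0(subject_id, "_meta.json"))
  if (!file.exists(meta_path)) stopf("no acquisition for %s in %s", subject_id, dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ovg <- as.matrix(utils::read.table(
    file.path(dir, paste0(subject_id, "_ovg.csv")), sep = ","))
  ppg <- as.matrix(utils::read.table(
    file.path(dir, paste0(subject_id, "_ppg.csv")), sep = ","))
  dimnames(ovg) <- NULL
  dimnames(ppg) <- NULL
  if (nrow(ovg) != 3L) stopf("corrupt OVG matrix for %s", subject_id)
  if (nrow(ppg) == 2L) rownames(ppg) <- c("red", "infrared")
  structure(list(
    subject_id = meta$subject_id, ovg = ovg, ppg = ppg,
    ovg_rate = meta$ovg_rate, ppg_rate = meta$ppg_rate,
    duration = meta$duration, config = signal_config(duration = meta$duration),
    truth = meta$truth
  ), class = "acquisition_record")
}
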