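test_that("cycle segmentation finds the beats the generator placed", {
  # 70 bpm over 60 s -> ~70 beats; onsets within 10 ms of truth
  rec <- make_record(lvedp = 9, duration = 60, seed = 81)
  cyc <- segment_cycles(rec)
  nb_true <- length(rec$truth$beat_onsets)
  expect_gte(nrow(cyc), nb_true - 2)
  expect_lte(nrow(cyc), nb_true)
  err <- vapply(cyc$onset, function(o) min(abs(rec$truth$beat_onsets - o)),
                numeric(1))
  expect_lte(median(err) * 1000, 10)
  # windows are ordered and non-overlapping within a beat
  expect_true(all(cyc$atrial_onset < cyc$atrial_offset))
  expect_true(all(cyc$atrial_offset <= cyc$vdep_start + 1e-9))
  expect_true(all(cyc$vdep_end <= cyc$vrep_start + 1e-9))

  # flat-line OVG raises the dedicated condition
  flat <- rec
  flat$ovg[] <- 0
  flat$ovg[1, 1] <- 0.024
  expect_error(segment_cycles(flat), class = "no_cycles_detected")
})

test_that("atrial duration variation is the sample SD and recovers the truth", {
  expect_equal(atrial_duration_variation(c(100, 100, 100)), 0)
  expect_equal(atrial_duration_variation(c(100, 110, 120)), 10)
  expect_error(atrial_duration_variation(100), "at least 2")

  # parameter recovery at jitter SD 8 ms over >= 200 beats
  cfg <- signal_config(duration = 180,
                       atrial_jitter_sd_ms = c(base = 8, slope = 0))
  rec <- make_record(lvedp = 9, seed = 82, config = cfg)
  cyc <- segment_cycles(rec)
  expect_gte(nrow(cyc), 200)
  se <- 8 / sqrt(2 * (nrow(cyc) - 1))
  expect_lt(abs(atrial_duration_variation(cyc) - 8), 3 * se)
})

test_that("phase-space embedding is the raw 3-channel coordinate map", {
  m <- matrix(0, 3, 100)
  expect_true(all(phase_space_embed(m) == 0))

  # circle in the z = 0 plane
  th <- seq(0, 4 * pi, length.out = 500)
  m <- rbind(cos(th), sin(th), 0)
  traj <- phase_space_embed(m)
  expect_lt(max(abs(sqrt(traj[, 1]^2 + traj[, 2]^2) - 1)), 1e-9)
  expect_true(all(traj[, 3] == 0))

  # arc length equals the brute-force consecutive-distance sum
  set.seed(1)
  m <- matrix(rnorm(30), 3, 10)
  traj <- phase_space_embed(m)
  arc <- sum(sqrt(rowSums(diff(traj)^2)))
  brute <- 0
  for (i in 1:9) brute <- brute + sqrt(sum((m[, i + 1] - m[, i])^2))
  expect_equal(arc, brute)

  expect_error(phase_space_embed(matrix(0, 2, 10)), "3 equal-length")
})

test_that("phase-space features scale and vanish as the geometry dictates", {
  cfg0 <- signal_config(duration = 20, atrial_jitter_sd_ms = c(base = 0, slope = 0),
                        repol_dispersion = c(base = 0, slope = 0),
                        heart_rate_sd_bpm = 0)
  rec <- make_record(lvedp = 9, seed = 83, config = cfg0)
  cyc <- segment_cycles(rec)
  ps <- phase_space_features(rec, cyc)
  # identical beats, zero jitter -> repolarization dispersion collapses to
  # the numerical floor (sub-sample timing + interpolation, well under 1% of
  # the 300 uV wave amplitude), far below any configured effect level
  expect_lt(ps$phase_space.repol_dispersion, 1)

  # doubling amplitudes doubles the atrial vector magnitude
  dbl <- rec
  dbl$ovg <- rec$ovg * 2
  ps2 <- phase_space_features(dbl, cyc)
  expect_equal(ps2$phase_space.atrial_vector_mag_mean,
               2 * ps$phase_space.atrial_vector_mag_mean, tolerance = 1e-6)

  # dispersion equals the brute-force mean pairwise aligned-segment distance
  segs <- list(matrix(0, 5, 3), matrix(1, 5, 3), matrix(3, 5, 3))
  got <- pulsespace:::repol_dispersion_pairs(segs)
  d12 <- sqrt(3) * 1; d13 <- sqrt(3) * 3; d23 <- sqrt(3) * 2
  expect_equal(got, mean(c(d12, d13, d23)))
})

test_that("PPG indicators recover the generator's pulse-base truth", {
  rec <- make_record(lvedp = 30, duration = 20, seed = 84)
  cyc <- segment_cycles(rec)
  pi_feats <- ppg_indicators(rec, cyc)
  truth <- rec$truth$pulse_base_values
  # noiseless: measured per-beat base equals truth, so the max matches a
  # value drawn by the generator exactly
  expect_true(all(cyc$ppg_base_value %in% truth))
  expect_true(pi_feats$ppg_indicator.base_max %in% truth)

  # +c translation moves base features by c, amplitude features not at all
  shifted <- rec
  shifted$ppg <- rec$ppg + 25
  cyc2 <- segment_cycles(shifted)
  pi2 <- ppg_indicators(shifted, cyc2)
  expect_equal(pi2$ppg_indicator.base_max,
               pi_feats$ppg_indicator.base_max + 25, tolerance = 1e-9)
  expect_equal(pi2$ppg_indicator.amp_mean,
               pi_feats$ppg_indicator.amp_mean, tolerance = 1e-6)
})

test_that("spectral, sync and respiration features match constructed signals", {
  rec <- make_record(lvedp = 9, duration = 60, seed = 85)
  cyc <- segment_cycles(rec)
  feats <- spectral_and_sync_features(rec, cyc)

  # generator uses a 200 ms onset-to-foot delay
  expect_lt(abs(feats$sync.delay_mean - 200), 10)

  # amplitude modulation at the configured 0.25 Hz respiration rate
  expect_lt(abs(feats$respiration.dominant_freq - 0.25), 0.02)

  # pure 10 Hz tone concentrates in the 5-15 Hz band
  tone <- rec
  tt <- (seq_len(ncol(rec$ovg)) - 1) / rec$ovg_rate
  tone$ovg <- matrix(rep(10 * sin(2 * pi * 10 * tt), 3), nrow = 3, byrow = TRUE)
  tf <- spectral_and_sync_features(tone, cyc)
  expect_gt(tf$ovg_spectral.bp_5_15, 0.99)
})

test_that("feature extraction is deterministic with a stable, finite schema", {
  rec <- make_record(lvedp = 15, duration = 12, seed = 86)
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  num <- f1[vapply(f1, is.numeric, logical(1))]
  expect_true(all(is.finite(as.matrix(num))))

  rec2 <- make_record(lvedp = 30, duration = 12, seed = 87)
  f3 <- extract_features(rec2)
  expect_identical(names(f1), names(f3))
})

test_that("configured effects separate elevated from non-elevated cohorts", {
  # strong effects; one feature per affected family discriminates at p < 0.01
  n_per <- 24
  cfg <- signal_config(duration = 12,
                       atrial_jitter_sd_ms = c(base = 2, slope = 12),
                       pulse_base = c(base = 1000, slope = 120),
                       repol_dispersion = c(base = 2, slope = 40))
  feat_for <- function(lvedp, seed) {
    extract_features(generate_signals(
      data.frame(subject_id = paste0("d", seed), lvedp = lvedp), cfg, seed = seed))
  }
  lo <- do.call(rbind, lapply(seq_len(n_per), function(i) feat_for(8, 300 + i)))
  hi <- do.call(rbind, lapply(seq_len(n_per), function(i) feat_for(30, 600 + i)))
  for (col in c("time_domain.atrial_duration_sd",
                "ppg_indicator.base_mean",
                "phase_space.repol_dispersion")) {
    p <- wilcox.test(hi[[col]], lo[[col]])$p.value
    expect_lt(p, 0.01)
  }
})
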