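# pulsespace

Phase-space electro-mechanical pulse-wave analysis for predicting elevated
left ventricular end-diastolic pressure (LVEDP), rebuilt as a fully
synthetic, testable R pipeline.

Elevated LVEDP (≥ 25 mmHg at catheterization, against a normal control of
≤ 12 mmHg) is the invasive reference for left-heart filling pressure. The
non-invasive approach implemented here records a three-channel orthogonal
voltage gradient (OVG, 8 kHz, 0.024 µV resolution) together with two-channel
photoplethysmography (PPG, 500 Hz), embeds the OVG as a 3-D phase-space
trajectory whose loops correspond to atrial/ventricular events, extracts
features from six families (time-domain, phase-space, PPG pulse-wave
indicators, spectral, OVG–PPG synchronization, respiration), and scores risk
with a 13-model ensemble (random forests, gradient-boosted trees, elastic
nets) as the mean of min–max normalized constituent outputs:

    score(x) = (1/13) · Σ_m clip[ (f_m(x) − min_m) / (max_m − min_m), 0, 1 ]

Because the clinical cohort is proprietary, the package ships a synthetic
cohort and signal generator with known ground truth (beat onsets, per-beat
atrial durations, pulse-base values, latent effect parameters), so every
downstream stage — QC gates (powerline SNR ≥ 57 dB, high-frequency SNR
≥ 19 dB, PPG saturation ≤ 5 %), segmentation, features, isolation-forest
outlier exclusion, ensemble training with repeated stratified 5-fold CV,
DeLong/Clopper–Pearson evaluation, LVEDP threshold sweeps, propensity
matching — is tested against parameter recovery rather than trust.

The package also implements the BNP-comparison analysis end to end: BNP
values for a non-cardiac-etiology cohort and an obese-HFpEF cohort are
simulated from their printed five-number summaries by piecewise-uniform
(boxplot-constrained) sampling, yielding AUC and threshold statistics over
1000 iterations, Bayesian post-test probability curves from constant
sensitivity/specificity, and the net reclassification index (NRI) of the ML
operating point (82 % sensitivity, 68 % specificity) over BNP at the 150 and
50 pg/mL thresholds.

It is aimed at methodologists who want a working, inspectable reference of
this class of diagnostic pipeline — for teaching, benchmarking, or as
scaffolding for their own signal-based classifiers.

## Worked example

```r
library(pulsespace)

cohort <- generate_cohort(6, cohort_config(), seed = 42)
cohort[, c("subject_id", "age", "gender", "bmi", "lvedp", "stratum")]
#>   subject_id  age gender  bmi lvedp      stratum
#> 1     S00001 77.7   male 27.0   7.1 non_elevated
#> 2     S00002 69.7 female 29.7   4.6 non_elevated
#> 3     S00003 81.7 female 38.7  23.9          mid
#> ...

rec <- generate_signals(cohort[1, ], signal_config(duration = 15), seed = 42)
rec
#> <acquisition_record S00001: OVG 3 x 120000 @ 8000 Hz, PPG 2 x 7500 @ 500 Hz, 15s, 17 beats>

assess_quality(rec)[, c("powerline_snr", "highfreq_snr", "saturation_fraction", "overall_pass")]
#>   powerline_snr highfreq_snr saturation_fraction overall_pass
#> 1      100.3952     85.05717                   0         TRUE
```

A clean record clears both SNR gates (100 and 85 dB against the 57 and
19 dB thresholds) with no saturated PPG samples. Features recover what the
generator planted — this subject's LVEDP is 7.1 mmHg, so the LVEDP-linked
effects sit at their baselines (atrial jitter ≈ 2 ms, pulse base ≈ 1000
units, 200 ms OVG→PPG delay):

```r
feats <- extract_features(rec)
round(unlist(feats[c("time_domain.atrial_duration_sd", "ppg_indicator.base_max",
                     "phase_space.repol_dispersion", "sync.delay_mean")]), 3)
#> time_domain.atrial_duration_sd         ppg_indicator.base_max
#>                          1.846                       1002.769
#>   phase_space.repol_dispersion                sync.delay_mean
#>                          2.125                        202.029
```

The BNP comparison, from the printed five-number summaries alone:

```r
sim <- simulate_bnp_performance(iterations = 1000, seed = 1)
subset(sim$aggregate, statistic %in% c("auc", "sens_150", "spec_150"))
#>   statistic  mean    lo    hi
#> 1       auc 0.654 0.590 0.717
#> 8  sens_150 0.848 0.772 0.924
#> 9  spec_150 0.415 0.353 0.473

nri_vs_bnp(0.82, 0.68, sim, threshold = 150)$mean   # 0.24 (95% CI 0.14-0.34)
post_test_probability(0.59, 0.82, 0.68, "positive") # 0.79
```

Simulated BNP discriminates elevated LVEDP with a mean AUC of 0.654; at the
150 pg/mL threshold the ML operating point nets a reclassification index of
0.24, and a positive ML result lifts a 59 % pre-test probability to 79 %.
The full two-phase study design (develop → freeze → blinded validation) runs
via `run_pipeline(run_config(...))`, which returns a manifest with subject
accounting per exclusion gate, the frozen model hash, and all validation
metrics.

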