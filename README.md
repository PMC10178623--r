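# ffrdev

Developmental analysis of frequency-following and cortical auditory
responses — with a synthetic EEG cohort generator so the whole chain runs
without any recorded infant data.

## What this package is for

Infants hearing lexical tones (pitch patterns that contrast word meaning)
produce two very different evoked responses in scalp EEG:

* the **frequency-following response (FFR)** — early-latency activity
  phase-locked to the stimulus fundamental frequency (F0), dominated by
  subcortical generators, which grows steadily with age regardless of
  whether the tone is native;
* the **long-latency response (LLR)** — a slow cortical wave dominated in
  infancy by a broad positivity (**P1**), whose latency shortens after
  about 6 months of age for *native* tones only (perceptual narrowing).

`ffrdev` implements, as a tested R package, the complete analysis pipeline
for a longitudinal infant cohort presented with three /ga/ syllables
(native rising /ga2/, 182–278 Hz; native falling /ga4/, 152–187 Hz;
non-native dipping /ga3/, 142–177 Hz; 1000 sweeps per block, 674 ms onset
asynchrony, alternating polarity):

1. **Simulation** — stimulus synthesis, per-sweep FFR/LLR generation with
   age-dependent gain and P1 morphology, artifact injection, and a mixed
   cross-sectional/longitudinal visit structure with attrition
   (`synthesize_stimulus`, `generate_ffr_block`, `generate_llr_block`,
   `generate_cohort`).
2. **Preprocessing** — zero-phase Butterworth filtering (80–1500 Hz order 8
   for FFR; 0.1–30 Hz order 4 for LLR), resampling to 3 kHz, epoching
   (−50..225 ms / −100..600 ms), ±25/±100 µV artifact rejection, block QC
   (>10% rejected or averaged max > 0.7 µV), averaging with baseline
   correction and the 300-epoch LLR cap (`preprocess_block`).
3. **FFR metrics** — SNR (`10·log10` post/pre mean-square ratio),
   autocorrelogram pitch strength, lower (120–260 Hz) and middle
   (260–750 Hz) band powers, intertrial-phase-coherence (ITPC) pitch
   contour and tracking accuracy against the 20 ms-shifted stimulus
   contour (`snr_db`, `pitch_strength`, `band_power`, `itpc`,
   `extract_pitch_contour`, `tracking_accuracy`).
4. **LLR metrics** — automatic P1 argmax detection over 0–600 ms and LLR
   SNR (`detect_p1`, `llr_snr`).
5. **Classification** — 13 time-point features across 0–150 ms of each
   averaged FFR, per-month (>10 observations) bootstrapped linear-SVM
   decoding of the three tones with real and permuted labels, and the
   accuracy-versus-age trend test (`build_features`, `bootstrap_classify`,
   `classify_by_month`, `accuracy_age_trend`).
6. **Group statistics** — mixed-effects `metric ~ age × tone` models with a
   subject random intercept, partial η² = F·df1/(F·df1+df2) and Bonferroni
   battery m = 13; Wilcoxon rank-sum tests across the 165-day cutoff
   (native pooled/averaged vs. non-native); normalized 42/400-day
   age-group effect sizes with 95% CIs; and the combined four-factor LME
   with split-by-response-type follow-ups (`fit_metric_lme`,
   `wilcoxon_cutoff`, `age_group_effect_sizes`, `combined_lme`).

## Worked example

```r
library(ffrdev)

stim <- synthesize_stimulus("ga2")        # rising tone, 182-278 Hz, 174 ms
prof <- subject_profile(noise_sd = 0.5, artifact_rate = 0)
blk  <- generate_ffr_block(prof, stim, seed = 2, n_sweeps = 1000)

pp  <- preprocess_block(blk, pipeline_config("ffr"))
pp$qc$accept
#> [1] TRUE

map <- itpc(pp$block, bad_mask = pp$bad_mask)
ctr <- extract_pitch_contour(map, time_range = 20 + c(0, stim$duration_ms))
range(ctr$f0_hz)
#> [1] 186.2579 276.7020
tracking_accuracy(ctr, stimulus_pitch_contour(stim), lag_ms = 20)$r2
#> [1] 0.9990051
```

The extracted contour spans essentially the nominal 182–278 Hz stimulus
range, and its correlation with the 20 ms-shifted stimulus contour
(r² ≈ 0.999 here) is the pitch-tracking accuracy; on real infant grand
averages values of ~0.91–0.97 indicate faithful subcortical pitch encoding.

An end-to-end run (simulate → preprocess → metrics → classification →
statistics, with a manifest and QC log):

```r
run_pipeline(list(seed = 11, n_subjects = 5, n_sweeps = 60, noise_sd = 2,
                  llr_noise_sd = 8, B = 20, min_obs = 3),
             out_dir = "out")
```

or from the command line:

```sh
Rscript -e 'ffrdev::ffrdev_cli()' run-all --config smoke.cfg --out out
```

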