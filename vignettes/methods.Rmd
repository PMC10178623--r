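---
title: "Models and methods: simulated developmental FFR/LLR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulated developmental FFR/LLR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ffrdev)
```

## The scientific problem

Infants' auditory systems encode speech at two time scales that mature very
differently. The *frequency-following response* (FFR) is scalp-recorded
activity phase-locked to the periodicity of a sound — in practice, to the
fundamental frequency (F0) trajectory of a spoken syllable — and is
dominated by subcortical generators at these frequencies. The *long-latency
response* (LLR) is a slow cortical potential which, in infancy, is dominated
by one broad positivity (P1) peaking a few hundred milliseconds after
stimulus onset. Recording both simultaneously while infants hear lexical
tones (pitch patterns that contrast word meaning — here two native Cantonese
tones, rising "25" and falling "21", and the non-native Mandarin dipping
tone "214") lets one ask whether early neural encoding matures with age
irrespective of language experience, while cortical responses develop
sensitivity to nativeness around six months — the *perceptual narrowing*
window.

`ffrdev` implements the full analysis chain for this design — and, because
infant EEG of this kind is not publicly available, a synthetic cohort
generator whose statistical structure matches what the analyses assume, so
that every stage is exercisable end to end with known ground truth.

## The synthetic world

`cohort_spec()` states the emulated world; its defaults are fixed once and
used everywhere:

* **Stimuli.** Three /ga/ syllables. F0 ranges 182–278 Hz (rising /ga2/),
  152–187 Hz (falling /ga4/), 142–177 Hz (dipping, non-native /ga3/).
  1000 sweeps per block, 500 ms interstimulus interval, 674 ms onset
  asynchrony — hence a 174 ms stimulus — presented in alternating polarity.
  The dipping tone is realized as a piecewise-linear fall to the range
  minimum at 60% of the duration followed by a rise to the range maximum;
  since a 2-1-4 contour cannot start *and* end on the nominal bounds, the
  onset sits at the Chao-digit-2 level between the dip (digit 1) and the
  endpoint (digit 4). Waveforms are harmonic complexes (F0 plus harmonics
  2–3 at 6 dB/harmonic roll-off).
* **FFR sweeps.** Each sweep is `gain(age) ×` an envelope-locked component
  that follows the F0 contour (harmonics 1–3), delayed by a 20 ms neural
  lag, plus a polarity-locked carrier component at the 5th harmonic
  (~0.7–1.4 kHz, the formant region) that flips sign with stimulus polarity
  and therefore cancels exactly under alternating-polarity averaging, plus
  an equal-power pink/white noise mixture (default 5 µV per sweep). The
  carrier must be spectrally disjoint from the envelope-locked part: if the
  two shared frequencies, the π phase alternation would cap intertrial
  coherence at ~0.71 even in clean data. Gain is linear in age
  (`0.8 + 0.0012/day`), chosen so that 1000-sweep averages span roughly
  0–10 dB SNR over the first two years; the lag optionally shortens with age
  (−0.006 ms/day) so that FFR latency matures much faster than P1 latency,
  the contrast the effect-size comparison is designed to detect.
* **LLR sweeps.** A Gaussian positivity (σ = 45 ms) whose latency and
  amplitude interpolate smoothly (logistic, 40-day scale) between young and
  old targets around the 165-day cutoff: native latency 280→240 ms,
  non-native 278→276 ms; amplitudes 5→7 µV (native) and 5→6.5 µV
  (non-native). Noise is 0.1–30 Hz band noise (20 µV per sweep).
* **Artifacts.** A profile-determined fraction of sweeps (default 2%)
  carries large in-band bursts (120 µV Gaussian-windowed 300 Hz tone for
  FFR; 180 µV slow deflections for LLR) so that amplitude-threshold
  rejection has real work to do. Nothing else about real artifacts (ocular,
  cardiac, movement spectra) is modelled.
* **Cohort.** 85 subjects enrolled under per-month recruitment quotas
  (entry months 0–14, heavier over the first half year, youngest entry
  23 days), up to 4 visits ~159 days apart (±7 days), 25% per-revisit
  attrition, ages capped at 750 days. Per visit: one block per tone per
  response kind. The quota design — standard practice when a developmental
  cohort must cover every age bin — guarantees, together with the revisit
  echoes, that each month from birth to 14 months delivers more than 10
  observations, which the monthly decoding analysis requires; pure random
  enrolment at n = 85 leaves months at the >10 boundary short in a
  substantial fraction of cohorts.

What a green test on this world does **not** establish: robustness to real
scalp EEG (multi-channel topography, non-stationary noise, ocular/muscle
artifacts), to imperfect stimulus timing, or to FFR morphologies beyond the
phase-locked harmonic model. The generator is a statistical stand-in, not a
biophysical model.

## Preprocessing

The two extraction pipelines follow a fixed order — filter → resample →
epoch → reject → average:

* Zero-phase Butterworth band-pass: order 8, 80–1500 Hz (FFR); order 4,
  0.1–30 Hz (LLR). No IIR filtering package is available in the target
  environment, so the filters are applied as the *squared magnitude
  response* of the stated design in the frequency domain with reflection
  padding — identical in magnitude to forward–backward (`filtfilt`)
  application and exactly zero-phase, which avoids any latency bias in P1
  or FFR lag estimates. On a 700 ms epoch the 0.1 Hz high-pass edge mainly
  removes the DC bin; this is the expected behaviour at that epoch length.
* Fourier resampling from 20 kHz to 3 kHz (`round(n · 3/20)` samples,
  duration preserved, content above the new Nyquist discarded).
* Epochs are half-open windows, −50..225 ms (FFR) and −100..600 ms (LLR),
  time 0 at stimulus onset.
* An epoch is rejected iff any sample exceeds ±25 µV (FFR) / ±100 µV (LLR).
  A block is rejected when more than 10% of sweeps are rejected (for
  1000-sweep blocks, the ">100 rejections" rule; the fraction governs other
  sizes) or when the averaged FFR exceeds 0.7 µV absolute maximum
  (stimulus-artifact screen). Averages are baseline-corrected over the
  pre-stimulus window; for LLR only the *first 300 good epochs* in recording
  order enter the average, because the cortical response habituates.

## FFR metrics

* **SNR**: `10·log10` of the post- (0–225 ms) to pre-stimulus (−50–0 ms)
  mean-square power ratio. The windows are configurable; the full nominal
  epoch segments are the defaults.
* **Pitch strength**: normalized (biased, lag-0 = 1) autocorrelogram; the
  swing between the first local maximum in the 2.5–12.5 ms lag range
  (80–400 Hz, covering all stimulus F0s with margin) and the minimum
  between lag 0 and that peak.
* **Band powers**: one-sided periodogram of the post-stimulus average,
  zero-padded to 4096 bins for stable band edges; *mean* power per bin in
  the lower (120–260 Hz) and middle (260–750 Hz) bands so bands of
  different widths are comparable. With the `"sum"` aggregate the bins are
  scaled so a spectral partition reproduces the time-domain mean square
  exactly (Parseval), which the tests assert to 1e-6.
* **ITPC**: per epoch, a Morlet-style decomposition implemented as Gaussian
  frequency-domain kernels (sd `f/n_cycles`) on 100–350 Hz in 2 Hz steps;
  coefficients are unit-normalized and averaged across epochs; the map is
  the magnitude of that mean (1 = perfect phase locking, `√(π/4n)` expected
  under independent noise).
* **Pitch contour**: the ITPC-maximizing frequency within 120–300 Hz along
  a sliding window. Three numerical choices matter and are documented
  config keys:
  1. *12-cycle wavelets* (not a shorter default): σ_f = f/12 ≈ 12–23 Hz is
     narrow enough for stable ridge extraction; shorter wavelets leave an
     argmax plateau that jitters by tens of Hz.
  2. *5 ms window/step with centroid refinement*: the wavelet's own
     temporal envelope already smooths in time; long box windows bias the
     ridge on frequency glides (a 40 ms box displaces the steepest stimulus
     contour by ~11 Hz at its end). Sub-grid localisation uses the
     coherence-weighted centroid within ±10 Hz of the argmax.
  3. *Edge reconstruction*: within ~15 ms of the contour support edges the
     wavelet integrates the chirp one-sidedly and drags the ridge toward
     interior frequencies (≈ slope × σ_t·√(2/π)); ridge estimates in that
     zone are replaced by linear extrapolation of the adjacent clean
     segment, clamped to the analysis range.
  The contour support is the 20 ms-lag-shifted stimulus span, which is
  known in an evoked design; without a stimulus reference, positions below
  half the peak coherence are discarded instead.
* **Tracking accuracy**: Pearson correlation (and r²) between the response
  contour and the stimulus contour shifted 20 ms later, interpolated onto
  the response contour's grid over the overlap. Constant contours are
  flagged degenerate with r² reported as 0.

A caveat worth stating: a literally noise-free block makes ITPC — a
phase-only statistic — equal 1 at every time-frequency cell (identical
epochs), so "noise-free" checks are run at negligible (0.5 µV) rather than
zero noise.

## LLR metrics

P1 is located as the raw argmax of the averaged waveform over 0–600 ms (no
smoothing — the peak is defined as a maximum; ties break to the earliest
latency, and an argmax landing on a window edge is flagged rather than
rejected). Amplitude is the baseline-corrected value at the argmax. LLR SNR
uses the −100–0 / 0–600 ms windows with the same dB convention as the FFR.

## Classification

Averaged FFRs are reduced to **13 features**: equally spaced samples across
0–150 ms (12.5 ms spacing) of the anti-alias low-passed waveform. A literal
120 Hz resampling of 150 ms would give 19 points; the stated 13-point
output is treated as authoritative, with the 19-point reading available via
`n_points`. Features are z-scored across all observations entering the
monthly analysis (the documented mild leakage relative to per-fold
scaling). Observations are binned by month (`floor(age/30.44)`); bins need
*more than* 10 observations. Per bin and per label type (real/permuted), B
bootstrap resamples are drawn (resamples missing a class are rejected and
logged); each is classified by a linear maximum-margin classifier
(one-vs-rest squared-hinge SVM, cost 1 — implemented in-package as no SVM
library is available in the target environment) under stratified 5-fold
cross-validation.

Because bootstrap resampling duplicates observations across CV folds, the
permutation null sits slightly *above* 1/3 (we measure ≈0.35 on
unstructured data) — the same optimism visible in the original analysis's
permuted mean of 36.3%. The real-vs-permuted contrast, not the absolute
level, is the meaningful quantity.

## Group statistics

* Per metric: `value ~ age × tone` with a subject random intercept
  (`nlme::lme`, REML), marginal (type-III style, sum-contrast) F tests,
  partial η² = F·df1/(F·df1+df2), and Bonferroni adjustment with battery
  size m = 13 (reverse-engineered from the reported raw/adjusted p ratios,
  ≈13 in all four reported cases). Denominator df follow nlme's
  within-group rule; the original denominator-df method is unknown, so this
  is a documented configuration choice.
* The 165-day cutoff analysis: Wilcoxon rank-sum (midranks, tie-corrected
  normal approximation without continuity correction; exact enumeration for
  small samples) of old vs. young, run for native tones both pooled and
  per-visit averaged, and for the non-native tone; effect size r = Z/√N.
* The 42/400-day comparison: within each (response kind × measure in {SNR,
  peak amplitude, peak latency}), values of the two extreme age groups are
  z-scored and regressed on the old-group indicator; the slope with its 95%
  CI is the normalized maturation effect size.
* The combined model: z-scored measures (latency sign-flipped so
  maturation is positive everywhere — a flagged interpretive choice, with a
  switch) in one LME with age category, tone, ERP type and measure as fixed
  effects (mains + two-way interactions; the reported analysis includes the
  age × ERP-type interaction) and subject random intercept, followed by
  split-by-ERP-type follow-ups of the age effect.

## Reproducibility

All randomness flows from one master seed through named, hashed substreams
(`derive_seed`), so every stage is bit-reproducible; generators refuse to
run without a seed. `run_pipeline()` streams blocks (generate → preprocess
→ metrics) so memory stays bounded, writes per-stage outputs plus a
manifest with md5 checksums, and re-runs byte-identically. Unit tests use
scaled-down sweep counts (60–300 instead of 1000) and reduced bootstrap
counts (B ≤ 50 instead of 10,000); thresholds and acceptance tolerances are
never scaled.

## Known limitations

Single-channel only (re-referencing is a pass-through); amplitude-threshold
artifact rejection only; the SVM is linear with fixed cost; no
normality screening battery; the dipping-tone onset level and all SI-only
analysis parameters (SNR windows, ITPC kernel widths, SVM hyperparameters)
are reasoned defaults exposed as configuration, not recovered values.
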