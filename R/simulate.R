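## Synthetic EEG cohort generator.
##
## The generator emulates the statistical structure the downstream analyses
## assume: phase-locked periodic responses (FFR) lagged ~20 ms with
## age-dependent gain, slow cortical waves dominated by a broad P1 positivity
## whose latency/amplitude depend on age group and stimulus nativeness, a
## 1/f + white noise floor, sporadic high-amplitude artifact sweeps, and a
## mixed cross-sectional/longitudinal visit structure with attrition.

# --- noise -----------------------------------------------------------------

# unit-variance pink (1/f amplitude) noise via spectral shaping
pink_noise <- function(n) {
  if (n < 2) return(stats::rnorm(n))
  white <- stats::rnorm(n)
  x <- stats::fft(white)
  k <- c(1, seq_len(n - 1)) # avoid division by zero at DC
  shape <- 1 / sqrt(k)
  shape[1] <- 0 # no DC
  x <- x * shape
  y <- Re(stats::fft(x, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# unit-variance noise band-limited to [lo, hi] Hz with 1/sqrt(f) rolloff
band_noise <- function(n, fs, lo, hi) {
  white <- stats::rnorm(n)
  x <- stats::fft(white)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq) # mirrored axis
  shape <- ifelse(freq >= lo & freq <= hi, 1 / sqrt(pmax(freq, lo)), 0)
  y <- Re(stats::fft(x * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# mixture used for FFR sweeps: equal-power pink + white, sd = 1
ffr_noise <- function(n) {
  sqrt(0.5) * pink_noise(n) + sqrt(0.5) * stats::rnorm(n)
}

# --- subject profiles ------------------------------------------------------

#' Create a synthetic subject profile
#'
#' Encodes the per-subject parameters the generator uses: the age-dependent
#' FFR gain (linear in age, in days), the P1 latency/amplitude targets for
#' young (<= 165 days) vs. old ages separately for native and non-native
#' tones, the sweep noise level and the artifact rate.
#'
#' @param subject_id Subject identifier.
#' @param visit_ages_days Ages (days) at each visit; all within [0, 750].
#' @param ffr_gain_intercept,ffr_gain_slope_per_day Dimensionless FFR gain
#'   `gain(age) = intercept + slope * age`.
#' @param ffr_lag_ms Neural lag of the phase-locked response at the cohort's
#'   mid age (ms); the contour-tracking analyses assume 20 ms.
#' @param ffr_lag_slope_ms_per_day Linear age trend of the lag around
#'   375 days (negative = latency shortens with maturation). Set to 0 for
#'   an exactly 20 ms-lagged block.
#' @param llr_p1_latency_ms Named numeric: `native_young`, `native_old`,
#'   `nonnative_young`, `nonnative_old` (ms).
#' @param llr_p1_amplitude_uv Same names, amplitudes in uV.
#' @param llr_p1_width_ms Gaussian width (sd) of the P1 bump.
#' @param noise_sd Per-sweep FFR noise sd (uV); > 0.
#' @param llr_noise_sd Per-sweep 0.1-30 Hz noise sd (uV).
#' @param artifact_rate Fraction of sweeps carrying injected high-amplitude
#'   artifacts, in [0, 1).
#' @param ffr_amp_uv,ffr_carrier_uv Per-sweep amplitude (uV) of the
#'   envelope-locked (polarity-invariant) and carrier-locked
#'   (polarity-flipping) response components at gain 1.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "s01",
                            visit_ages_days = 100,
                            ffr_gain_intercept = 0.8,
                            ffr_gain_slope_per_day = 0.0012,
                            ffr_lag_ms = 20,
                            ffr_lag_slope_ms_per_day = 0,
                            llr_p1_latency_ms = c(native_young = 280,
                                                  native_old = 240,
                                                  nonnative_young = 278,
                                                  nonnative_old = 276),
                            llr_p1_amplitude_uv = c(native_young = 5,
                                                    native_old = 7,
                                                    nonnative_young = 5,
                                                    nonnative_old = 6.5),
                            llr_p1_width_ms = 45,
                            noise_sd = 5,
                            llr_noise_sd = 20,
                            artifact_rate = 0.02,
                            ffr_amp_uv = 0.15,
                            ffr_carrier_uv = 0.15) {
  assert_that(all(visit_ages_days >= 0 & visit_ages_days <= 750),
              "visit ages must lie within [0, 750] days")
  assert_that(artifact_rate >= 0 && artifact_rate < 1,
              "artifact_rate must be in [0, 1)")
  assert_that(noise_sd >= 0 && llr_noise_sd >= 0, "noise sd must be >= 0")
  structure(list(
    subject_id = subject_id, visit_ages_days = visit_ages_days,
    ffr_gain_intercept = ffr_gain_intercept,
    ffr_gain_slope_per_day = ffr_gain_slope_per_day,
    ffr_lag_ms = ffr_lag_ms,
    ffr_lag_slope_ms_per_day = ffr_lag_slope_ms_per_day,
    llr_p1_latency_ms = llr_p1_latency_ms,
    llr_p1_amplitude_uv = llr_p1_amplitude_uv,
    llr_p1_width_ms = llr_p1_width_ms,
    noise_sd = noise_sd, llr_noise_sd = llr_noise_sd,
    artifact_rate = artifact_rate,
    ffr_amp_uv = ffr_amp_uv, ffr_carrier_uv = ffr_carrier_uv
  ), class = "subject_profile")
}

ffr_gain <- function(profile, age_days) {
  max(profile$ffr_gain_intercept + profile$ffr_gain_slope_per_day * age_days,
      0.05)
}

ffr_lag <- function(profile, age_days) {
  profile$ffr_lag_ms + profile$ffr_lag_slope_ms_per_day * (age_days - 375)
}

# smooth young->old transition centred at the 165-day cutoff
age_mix <- function(age_days, cutoff = 165, scale = 40) {
  stats::plogis((age_days - cutoff) / scale)
}

llr_param <- function(values, nativeness, age_days) {
  w <- age_mix(age_days)
  y <- values[[paste0(nativeness, "_young")]]
  o <- values[[paste0(nativeness, "_old")]]
  (1 - w) * y + w * o
}

# --- epoch blocks ----------------------------------------------------------

new_epoch_block <- function(epochs, time_ms, sampling_rate, polarity,
                            subject_id, age_days, tone_id, nativeness,
                            response_kind, n_artifacts = 0L,
                            qc_state = "raw") {
  structure(list(
    subject_id = subject_id, age_days = age_days,
    tone_id = tone_id, nativeness = nativeness,
    sampling_rate_hz = sampling_rate,
    epochs = epochs, time_ms = time_ms, polarity = polarity,
    response_kind = response_kind,
    n_artifacts_injected = as.integer(n_artifacts),
    qc_state = qc_state
  ), class = "epoch_block")
}

#' @export
print.epoch_block <- function(x, ...) {
  cat(sprintf("<epoch_block> %s %s %s: %d sweeps x %d samples @ %g Hz, [%g, %g) ms, qc=%s\n",
              x$subject_id, x$tone_id, toupper(x$response_kind),
              nrow(x$epochs), ncol(x$epochs), x$sampling_rate_hz,
              x$time_ms[1], x$time_ms[length(x$time_ms)] + 1000 / x$sampling_rate_hz,
              x$qc_state))
  invisible(x)
}

# time axis for a half-open window [w1, w2) ms
epoch_time_axis <- function(window_ms, fs) {
  n <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  window_ms[1] + (seq_len(n) - 1) / fs * 1000
}

# in-band artifact burst (Gaussian-windowed tone) exceeding the rejection
# threshold even after band-pass filtering
artifact_burst <- function(time_ms, centre_ms, freq_hz, amp_uv, width_ms) {
  amp_uv * exp(-(time_ms - centre_ms)^2 / (2 * width_ms^2)) *
    sin(2 * pi * freq_hz * (time_ms - centre_ms) / 1000)
}

# deterministic noise-free FFR template for one polarity at a given age:
# envelope-locked harmonic complex following the F0 contour, delayed by the
# neural lag; plus the polarity-locked carrier (a 90 deg-shifted copy).
ffr_template <- function(profile, stimulus, age_days, time_ms) {
  lag <- ffr_lag(profile, age_days)
  gain <- ffr_gain(profile, age_days)
  fs <- stimulus$sampling_rate
  # map epoch times onto the stimulus contour, shifted by the lag
  t_rel <- time_ms - lag
  inside <- t_rel >= 0 & t_rel < stimulus$duration_ms
  env <- numeric(length(time_ms))
  car <- numeric(length(time_ms))
  if (any(inside)) {
    idx <- pmin(pmax(round(t_rel[inside] * fs / 1000) + 1, 1),
                length(stimulus$f0_contour))
    ph <- contour_phase(stimulus$f0_contour, fs)[idx]
    e <- numeric(length(ph))
    for (h in seq_along(HARMONIC_AMPS)) {
      e <- e + HARMONIC_AMPS[h] * sin(2 * pi * h * ph)
    }
    # carrier-locked energy sits in the formant region (5th harmonic,
    # ~0.7-1.4 kHz), spectrally disjoint from the F0-locked component
    cpart <- cos(2 * pi * 5 * ph)
    # smooth 5 ms onset/offset ramps so the response has no step edges
    tt <- t_rel[inside]
    ramp <- pmin(1, tt / 5) * pmin(1, (stimulus$duration_ms - tt) / 5)
    env[inside] <- e * ramp
    car[inside] <- cpart * ramp
  }
  list(envelope = gain * profile$ffr_amp_uv * env,
       carrier = profile$ffr_carrier_uv * car)
}

#' Generate one synthetic FFR epoch block
#'
#' Each sweep is `gain(age) x` an envelope-locked F0-following component
#' delayed by the neural lag (polarity-invariant, so alternating-polarity
#' averaging preserves it), plus a polarity-locked carrier component that
#' cancels under alternating-polarity averaging, plus a pink/white noise
#' mixture. A profile-determined fraction of sweeps carries injected
#' high-amplitude in-band artifact bursts.
#'
#' @param profile A [subject_profile()].
#' @param stimulus A [synthesize_stimulus()] spec (its sampling rate is the
#'   recording rate).
#' @param seed Mandatory integer seed.
#' @param age_days Age at the visit; defaults to the profile's first visit.
#' @param n_sweeps Number of sweeps; defaults to the stimulus block size.
#' @param window_ms Epoch window (half-open, ms re stimulus onset).
#' @param artifact_placement `"random"` or `"first"` (deterministic: the
#'   first `round(rate * n)` sweeps carry artifacts).
#' @return An `epoch_block` (`response_kind = "ffr"`).
#' @export
generate_ffr_block <- function(profile, stimulus, seed,
                               age_days = profile$visit_ages_days[1],
                               n_sweeps = stimulus$n_sweeps,
                               window_ms = c(-50, 225),
                               artifact_placement = c("random", "first")) {
  artifact_placement <- match.arg(artifact_placement)
  assert_that(window_ms[1] <= -50 && window_ms[2] >= 225,
              "FFR sweeps must span at least -50..225 ms")
  fs <- stimulus$sampling_rate
  time_ms <- epoch_time_axis(window_ms, fs)
  tmpl <- ffr_template(profile, stimulus, age_days, time_ms)
  n <- as.integer(n_sweeps)
  assert_that(n >= 1, "n_sweeps must be >= 1")
  polarity <- rep_len(c(1L, -1L), n)
  n_art <- round(profile$artifact_rate * n)
  with_seed(seed, {
    art_idx <- if (n_art > 0) {
      if (artifact_placement == "first") seq_len(n_art) else
        sample.int(n, n_art)
    } else integer(0)
    ns <- length(time_ms)
    epochs <- matrix(0, nrow = n, ncol = ns)
    for (i in seq_len(n)) {
      sweep <- tmpl$envelope + polarity[i] * tmpl$carrier
      if (profile$noise_sd > 0) sweep <- sweep + profile$noise_sd * ffr_noise(ns)
      epochs[i, ] <- sweep
    }
    for (i in art_idx) {
      centre <- stats::runif(1, window_ms[1] + 20, window_ms[2] - 20)
      epochs[i, ] <- epochs[i, ] +
        artifact_burst(time_ms, centre, freq_hz = 300, amp_uv = 120,
                       width_ms = 10)
    }
    new_epoch_block(epochs, time_ms, fs, polarity,
                    profile$subject_id, age_days, stimulus$tone_id,
                    stimulus$nativeness, "ffr", n_artifacts = length(art_idx))
  })
}

#' Generate one synthetic LLR epoch block
#'
#' Sweeps contain a broad positive deflection (Gaussian bump) whose latency
#' and amplitude follow the profile's young/old, native/non-native targets
#' (smoothly interpolated around the 165-day cutoff), plus 0.1-30 Hz band
#' noise; a fraction of sweeps carries slow high-amplitude artifacts.
#'
#' @inheritParams generate_ffr_block
#' @param window_ms Epoch window; must span at least -100..600 ms.
#' @return An `epoch_block` (`response_kind = "llr"`).
#' @export
generate_llr_block <- function(profile, stimulus, seed,
                               age_days = profile$visit_ages_days[1],
                               n_sweeps = stimulus$n_sweeps,
                               window_ms = c(-100, 600),
                               artifact_placement = c("random", "first")) {
  artifact_placement <- match.arg(artifact_placement)
  assert_that(window_ms[1] <= -100 && window_ms[2] >= 600,
              "LLR sweeps must span at least -100..600 ms")
  fs <- stimulus$sampling_rate
  time_ms <- epoch_time_axis(window_ms, fs)
  lat <- llr_param(profile$llr_p1_latency_ms, stimulus$nativeness, age_days)
  amp <- llr_param(profile$llr_p1_amplitude_uv, stimulus$nativeness, age_days)
  bump <- amp * exp(-(time_ms - lat)^2 / (2 * profile$llr_p1_width_ms^2))
  n <- as.integer(n_sweeps)
  assert_that(n >= 1, "n_sweeps must be >= 1")
  polarity <- rep_len(c(1L, -1L), n)
  n_art <- round(profile$artifact_rate * n)
  with_seed(seed, {
    art_idx <- if (n_art > 0) {
      if (artifact_placement == "first") seq_len(n_art) else
        sample.int(n, n_art)
    } else integer(0)
    ns <- length(time_ms)
    epochs <- matrix(0, nrow = n, ncol = ns)
    for (i in seq_len(n)) {
      sweep <- bump
      if (profile$llr_noise_sd > 0) {
        sweep <- sweep + profile$llr_noise_sd * band_noise(ns, fs, 0.1, 30)
      }
      epochs[i, ] <- sweep
    }
    for (i in art_idx) {
      centre <- stats::runif(1, window_ms[1] + 100, window_ms[2] - 100)
      epochs[i, ] <- epochs[i, ] +
        180 * exp(-(time_ms - centre)^2 / (2 * 80^2))
    }
    new_epoch_block(epochs, time_ms, fs, polarity,
                    profile$subject_id, age_days, stimulus$tone_id,
                    stimulus$nativeness, "llr", n_artifacts = length(art_idx))
  })
}

# --- cohorts ---------------------------------------------------------------

#' Cohort specification
#'
#' Defaults state the emulated world: 85 infants/toddlers, up to 4 visits
#' about 159 days (5.2 months) apart with +/- 7 day jitter, per-visit
#' Bernoulli attrition, and per visit one block of 1000 sweeps for each of
#' the three tones (and each response kind). Enrolment follows per-month
#' recruitment quotas (heavier over the first half year, the way
#' developmental cohorts are recruited) covering entry months 0-14, so that
#' together with the revisit echoes every month of age from birth to 14
#' months delivers more than 10 observations -- the coverage the monthly
#' decoding analysis assumes.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param entry_min_days Youngest possible entry age (days).
#' @param entry_quota Recruitment weights over entry months (month 0 is the
#'   first element); subjects are allocated to entry months by largest
#'   remainder and drawn uniformly within their month.
#' @param max_visits Maximum visits per subject.
#' @param visit_interval_days,visit_jitter_days Spacing of revisits.
#' @param attrition Per-revisit dropout probability.
#' @param age_cap_days Visits beyond this age are not scheduled.
#' @param n_sweeps Sweeps per block.
#' @param sampling_rate Recording rate (Hz).
#' @param tones Tone blocks per visit.
#' @param response_kinds Which response kinds to simulate.
#' @param noise_sd,llr_noise_sd,artifact_rate Population-level means for the
#'   subject profiles (each subject gets mild random variation).
#' @param ffr_gain_slope_per_day Population mean FFR maturation slope.
#' @param ffr_lag_slope_ms_per_day Population FFR latency maturation slope.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 85,
                        entry_min_days = 23,
                        entry_quota = c(9, 8, 8, 8, 8, 8, 4, 4, 4, 4,
                                        3, 3, 3, 3, 3),
                        max_visits = 4,
                        visit_interval_days = 159,
                        visit_jitter_days = 7,
                        attrition = 0.25,
                        age_cap_days = 750,
                        n_sweeps = 1000,
                        sampling_rate = 20000,
                        tones = c("ga2", "ga4", "ga3"),
                        response_kinds = c("ffr", "llr"),
                        noise_sd = 5,
                        llr_noise_sd = 20,
                        artifact_rate = 0.02,
                        ffr_gain_slope_per_day = 0.0012,
                        ffr_lag_slope_ms_per_day = -0.006) {
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Draw the subject/visit table for a cohort
#'
#' Cheap (no EEG is generated): per subject, an entry age, revisit ages and
#' attrition are drawn, producing the mixed cross-sectional/longitudinal
#' visit structure.
#'
#' @param spec A [cohort_spec()].
#' @param seed Mandatory seed.
#' @return data.frame: `subject_id`, `visit`, `age_days`.
#' @export
cohort_visits <- function(spec, seed) {
  with_seed(seed, {
    entry_month <- quota_allocate(spec$entry_quota, spec$n_subjects)
    rows <- list()
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("s%03d", s)
      m <- entry_month[s]
      a1 <- stats::runif(1, max(spec$entry_min_days, m * DAYS_PER_MONTH),
                         (m + 1) * DAYS_PER_MONTH)
      ages <- a1
      for (v in seq_len(spec$max_visits - 1)) {
        if (stats::runif(1) < spec$attrition) break
        nxt <- ages[length(ages)] + spec$visit_interval_days +
          stats::runif(1, -spec$visit_jitter_days, spec$visit_jitter_days)
        if (nxt > spec$age_cap_days) break
        ages <- c(ages, nxt)
      }
      rows[[s]] <- data.frame(subject_id = sid,
                              visit = seq_along(ages),
                              age_days = as.integer(round(ages)),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

# Largest-remainder allocation of n subjects to entry months with the given
# quota weights; returns one entry month per subject (0-based).
quota_allocate <- function(weights, n) {
  target <- weights / sum(weights) * n
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(seq_along(weights) - 1L, counts)
}

# per-subject profile with mild population variation
draw_profile <- function(spec, subject_id, visit_ages, seed) {
  with_seed(seed, {
    subject_profile(
      subject_id = subject_id,
      visit_ages_days = visit_ages,
      ffr_gain_intercept = max(0.2, stats::rnorm(1, 0.8, 0.1)),
      ffr_gain_slope_per_day = stats::rnorm(1, spec$ffr_gain_slope_per_day,
                                            abs(spec$ffr_gain_slope_per_day) / 4),
      ffr_lag_ms = 20,
      ffr_lag_slope_ms_per_day = spec$ffr_lag_slope_ms_per_day,
      llr_p1_latency_ms = c(native_young = stats::rnorm(1, 280, 8),
                            native_old = stats::rnorm(1, 240, 8),
                            nonnative_young = stats::rnorm(1, 278, 8),
                            nonnative_old = stats::rnorm(1, 276, 8)),
      llr_p1_amplitude_uv = c(native_young = max(1, stats::rnorm(1, 5, 0.8)),
                              native_old = max(1, stats::rnorm(1, 7, 0.8)),
                              nonnative_young = max(1, stats::rnorm(1, 5, 0.8)),
                              nonnative_old = max(1, stats::rnorm(1, 6.5, 0.8))),
      noise_sd = spec$noise_sd * stats::runif(1, 0.8, 1.25),
      llr_noise_sd = spec$llr_noise_sd * stats::runif(1, 0.8, 1.25),
      artifact_rate = stats::runif(1, 0.2, 1.8) * spec$artifact_rate
    )
  })
}

block_seed <- function(seed, subject_id, visit, tone, kind) {
  derive_seed(seed, subject_id, visit, tone, kind)
}

#' Generate a full synthetic cohort in memory
#'
#' For large cohorts prefer [run_pipeline()], which streams blocks to disk;
#' this materialises every epoch matrix.
#'
#' @param spec A [cohort_spec()].
#' @param seed Mandatory master seed; all per-subject and per-block seeds are
#'   derived from it.
#' @return A list of class `cohort`: `visits` (data.frame), `profiles`,
#'   `blocks` (list of `epoch_block`), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed) {
  visits <- cohort_visits(spec, seed)
  stimuli <- lapply(spec$tones, synthesize_stimulus,
                    sampling_rate = spec$sampling_rate)
  names(stimuli) <- spec$tones
  profiles <- list()
  blocks <- list()
  for (sid in unique(visits$subject_id)) {
    vs <- visits[visits$subject_id == sid, ]
    prof <- draw_profile(spec, sid, vs$age_days, derive_seed(seed, sid, "prof"))
    profiles[[sid]] <- prof
    for (v in vs$visit) {
      age <- vs$age_days[vs$visit == v]
      for (tone in spec$tones) {
        for (kind in spec$response_kinds) {
          bs <- block_seed(seed, sid, v, tone, kind)
          blk <- if (kind == "ffr") {
            generate_ffr_block(prof, stimuli[[tone]], bs, age_days = age,
                               n_sweeps = spec$n_sweeps)
          } else {
            generate_llr_block(prof, stimuli[[tone]], bs, age_days = age,
                               n_sweeps = spec$n_sweeps)
          }
          blocks[[paste(sid, v, tone, kind, sep = "_")]] <- blk
        }
      }
    }
  }
  structure(list(visits = visits, profiles = profiles, blocks = blocks,
                 spec = spec, seed = seed), class = "cohort")
}

#' Simulate a long-format metrics table directly
#'
#' Draws metric values from the linear mixed model the inferential layer
#' assumes (`value = b0 + b_age * age + tone effects + age x tone
#' interaction + subject random intercept + residual`), bypassing EEG
#' synthesis. Used for statistical calibration experiments (parameter
#' recovery, type-I error) where hundreds of replicate cohorts are needed.
#'
#' @param spec A [cohort_spec()] (only the visit structure is used).
#' @param seed Mandatory seed.
#' @param b0,b_age Intercept and age slope (units of the metric per day).
#' @param b_tone Named offsets for tones beyond the first (default 0).
#' @param b_interaction Age x tone slope offsets for tones beyond the first.
#' @param re_sd,sigma Random-intercept and residual standard deviations.
#' @return data.frame: subject_id, visit, age_days, tone, nativeness, value.
#' @export
simulate_metrics <- function(spec, seed, b0 = 0, b_age = 0,
                             b_tone = c(0, 0), b_interaction = c(0, 0),
                             re_sd = 1, sigma = 1) {
  visits <- cohort_visits(spec, derive_seed(seed, "visits"))
  tones <- spec$tones
  tt <- tone_table()
  with_seed(derive_seed(seed, "metrics"), {
    subj <- unique(visits$subject_id)
    re <- stats::setNames(stats::rnorm(length(subj), 0, re_sd), subj)
    rows <- visits[rep(seq_len(nrow(visits)), each = length(tones)), ]
    rows$tone <- rep(tones, times = nrow(visits))
    rows$nativeness <- tt$nativeness[match(rows$tone, tt$tone_id)]
    tone_idx <- match(rows$tone, tones) - 1L # 0 for reference tone
    tone_off <- ifelse(tone_idx == 0, 0, b_tone[pmax(tone_idx, 1)])
    int_off <- ifelse(tone_idx == 0, 0, b_interaction[pmax(tone_idx, 1)])
    rows$value <- b0 + b_age * rows$age_days + tone_off +
      int_off * rows$age_days + re[rows$subject_id] +
      stats::rnorm(nrow(rows), 0, sigma)
    rownames(rows) <- NULL
    rows
  })
}
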