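# Shared fixtures, built once per test run and memoised. Sweep counts are
# scaled down from the full-scale 1000-sweep blocks to keep the suite fast;
# noise levels are the generator's low-noise setting so ridge structure is
# identifiable at small n.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

quiet_profile <- function(...) {
  subject_profile(noise_sd = 0, llr_noise_sd = 0, artifact_rate = 0, ...)
}

# low-noise preprocessed FFR block + ITPC map for a tone (shared by the
# ffr-metrics and acceptance tests)
tracked_block <- function(tone, n_sweeps = 300, noise_sd = 0.5, seed = 2) {
  fixture(paste0("tracked_", tone, "_", n_sweeps, "_", seed), function() {
    prof <- subject_profile(noise_sd = noise_sd, artifact_rate = 0)
    stim <- synthesize_stimulus(tone)
    blk <- generate_ffr_block(prof, stim, seed = seed, n_sweeps = n_sweeps)
    pp <- preprocess_block(blk, pipeline_config("ffr"))
    map <- itpc(pp$block, bad_mask = pp$bad_mask)
    contour <- extract_pitch_contour(map,
                                     time_range = 20 + c(0, stim$duration_ms))
    list(stim = stim, pp = pp, map = map, contour = contour)
  })
}

# small multi-subject set of averaged FFRs for feature/classification tests
small_ffr_averages <- function() {
  fixture("small_ffr_averages", function() {
    avgs <- list()
    i <- 0
    for (s in 1:8) {
      for (tone in c("ga2", "ga4", "ga3")) {
        i <- i + 1
        prof <- subject_profile(subject_id = sprintf("s%02d", s),
                                noise_sd = 2, artifact_rate = 0)
        stim <- synthesize_stimulus(tone)
        blk <- generate_ffr_block(prof, stim, seed = 100 * s + i,
                                  age_days = 40, n_sweeps = 60)
        avgs[[i]] <- preprocess_block(blk, pipeline_config("ffr"))$averaged
      }
    }
    avgs
  })
}

# build an epoch_block directly from a matrix (cheap synthetic input)
matrix_block <- function(epochs, fs = 3000, t0_ms = -50, kind = "ffr") {
  time_ms <- t0_ms + (seq_len(ncol(epochs)) - 1) / fs * 1000
  structure(list(
    subject_id = "sx", age_days = 100, tone_id = "ga2",
    nativeness = "native", sampling_rate_hz = fs,
    epochs = epochs, time_ms = time_ms,
    polarity = rep_len(c(1L, -1L), nrow(epochs)),
    response_kind = kind, n_artifacts_injected = 0L, qc_state = "raw"
  ), class = "epoch_block")
}

# averaged_response constructed directly
make_avg <- function(waveform, fs = 3000, t0_ms = -100, kind = "llr") {
  structure(list(
    waveform = waveform,
    time_ms = t0_ms + (seq_along(waveform) - 1) / fs * 1000,
    n_epochs_used = 1L, subject_id = "sx", age_days = 100,
    tone_id = "ga2", nativeness = "native", response_kind = kind,
    sampling_rate_hz = fs
  ), class = "averaged_response")
}
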