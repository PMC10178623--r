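## Raw sweeps -> QC'd averaged waveforms, for the two extraction pipelines.
##
## Fixed order of operations: filter (zero-phase, on the raw sweeps) ->
## resample to the target rate -> epoch (when the input is continuous) ->
## amplitude-based artifact rejection -> block-level QC -> average with
## baseline correction. FFR: 8th-order 80-1500 Hz band-pass, -50..225 ms
## epochs, +/-25 uV rejection, block rejected when >10% of sweeps are bad or
## the averaged maximum exceeds 0.7 uV. LLR: 4th-order 0.1-30 Hz band-pass,
## -100..600 ms epochs, +/-100 uV rejection, and only the first 300 good
## epochs enter the average (the long-latency response habituates).

#' Pipeline configuration
#'
#' @param response `"ffr"` or `"llr"`; selects the documented defaults.
#' @param ... Overrides for individual keys (`band`, `filter_order`,
#'   `target_rate`, `epoch_ms`, `reject_uv`, `block_reject_frac`,
#'   `avg_max_uv`, `epoch_cap`, `baseline_ms`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(response = c("ffr", "llr"), ...) {
  response <- match.arg(response)
  cfg <- if (response == "ffr") {
    list(response = "ffr", band = c(80, 1500), filter_order = 8,
         target_rate = 3000, epoch_ms = c(-50, 225), reject_uv = 25,
         block_reject_frac = 0.1, avg_max_uv = 0.7, epoch_cap = Inf,
         baseline_ms = c(-50, 0))
  } else {
    list(response = "llr", band = c(0.1, 30), filter_order = 4,
         target_rate = 3000, epoch_ms = c(-100, 600), reject_uv = 100,
         block_reject_frac = NA_real_, avg_max_uv = Inf, epoch_cap = 300,
         baseline_ms = c(-100, 0))
  }
  dots <- list(...)
  for (k in names(dots)) {
    if (!k %in% names(cfg)) stop("unknown pipeline_config key: ", k)
    cfg[[k]] <- dots[[k]]
  }
  assert_that(cfg$reject_uv > 0 && cfg$target_rate > 0,
              "thresholds and rates must be > 0")
  assert_that(cfg$epoch_ms[1] < 0 && cfg$epoch_ms[2] > 0,
              "epoch window must contain stimulus onset")
  assert_that(cfg$epoch_cap >= 1, "epoch cap must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Extract epochs from a continuous recording
#'
#' @param x Continuous single-channel signal (uV).
#' @param onsets Stimulus-onset sample indices (1-based).
#' @param window_ms Half-open epoch window `[start, end)` in ms re onset.
#' @param fs Sampling rate (Hz).
#' @param ... Metadata passed to the block (subject_id, age_days, tone_id,
#'   nativeness, response_kind, polarity).
#' @return An `epoch_block`; onsets whose epoch would fall outside the
#'   recording are dropped and reported in `attr(, "dropped")` and a message.
#' @export
extract_epochs <- function(x, onsets, window_ms, fs,
                           subject_id = NA_character_, age_days = NA_real_,
                           tone_id = NA_character_, nativeness = NA_character_,
                           response_kind = "ffr", polarity = NULL) {
  n <- length(x)
  off1 <- round(window_ms[1] * fs / 1000)
  nsamp <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  starts <- onsets + off1
  ok <- starts >= 1 & (starts + nsamp - 1) <= n
  if (any(!ok)) {
    message(sum(!ok), " epoch(s) dropped: too close to the recording edge")
  }
  assert_that(any(ok), "no epoch fits inside the recording")
  epochs <- t(vapply(starts[ok], function(s) x[s:(s + nsamp - 1)],
                     numeric(nsamp)))
  pol <- if (is.null(polarity)) rep_len(c(1L, -1L), length(onsets))[ok]
         else polarity[ok]
  blk <- new_epoch_block(epochs, epoch_time_axis(window_ms, fs), fs, pol,
                         subject_id, age_days, tone_id, nativeness,
                         response_kind)
  attr(blk, "dropped") <- which(!ok)
  blk
}

#' Flag artifact epochs by amplitude threshold
#'
#' An epoch is bad iff any sample's absolute value exceeds the threshold.
#'
#' @param block An `epoch_block` (or a plain epochs matrix).
#' @param threshold_uv Rejection threshold in uV (> 0).
#' @return Logical vector, `TRUE` = bad, one element per sweep.
#' @export
reject_artifacts <- function(block, threshold_uv) {
  assert_that(threshold_uv > 0, "threshold must be > 0")
  epochs <- if (inherits(block, "epoch_block")) block$epochs else block
  apply(abs(epochs) > threshold_uv, 1, any)
}

#' Block-level quality control
#'
#' A block is rejected when the rejected-sweep fraction exceeds
#' `block_reject_frac` (for 1000-sweep blocks the documented >100-rejection
#' rule), or when the averaged waveform's absolute maximum exceeds
#' `avg_max_uv` (stimulus-artifact screen). The decision is a pure function
#' of its inputs.
#'
#' @param bad_mask Logical vector from [reject_artifacts()].
#' @param averaged An `averaged_response` (or waveform vector); may be NULL
#'   when no epoch survived.
#' @param config A [pipeline_config()].
#' @return list(accept, reason, rejected_count, n_good).
#' @export
qc_block <- function(bad_mask, averaged, config) {
  n <- length(bad_mask)
  rejected <- sum(bad_mask)
  reason <- "ok"
  accept <- TRUE
  if (!is.na(config$block_reject_frac) && rejected > config$block_reject_frac * n) {
    accept <- FALSE
    reason <- sprintf("rejected sweeps %d/%d exceed %g%% limit",
                      rejected, n, 100 * config$block_reject_frac)
  } else if (rejected == n) {
    accept <- FALSE
    reason <- "no good epochs"
  } else if (is.finite(config$avg_max_uv) && !is.null(averaged)) {
    w <- if (inherits(averaged, "averaged_response")) averaged$waveform else averaged
    if (max(abs(w)) > config$avg_max_uv) {
      accept <- FALSE
      reason <- sprintf("averaged max %.3g uV exceeds %g uV stimulus-artifact screen",
                        max(abs(w)), config$avg_max_uv)
    }
  }
  list(accept = accept, reason = reason, rejected_count = rejected,
       n_good = n - rejected)
}

#' Average good epochs with baseline correction
#'
#' @param block An `epoch_block`.
#' @param bad_mask Logical bad-epoch mask (default: none bad).
#' @param baseline_ms Half-open baseline window whose mean is subtracted.
#' @param cap When finite, only the first `cap` good epochs (in recording
#'   order) enter the average.
#' @return An `averaged_response`: `waveform`, `time_ms`, `n_epochs_used`,
#'   block metadata, `response_kind`.
#' @export
average_epochs <- function(block, bad_mask = NULL, baseline_ms = NULL,
                           cap = Inf) {
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, nrow(block$epochs))
  good <- which(!bad_mask)
  assert_that(length(good) >= 1, "no good epochs to average")
  if (is.finite(cap)) good <- good[seq_len(min(cap, length(good)))]
  w <- colMeans(block$epochs[good, , drop = FALSE])
  if (!is.null(baseline_ms)) {
    bi <- window_index(block$time_ms, baseline_ms)
    assert_that(length(bi) > 0, "baseline window outside the epoch")
    w <- w - mean(w[bi])
  }
  structure(list(
    waveform = w, time_ms = block$time_ms,
    n_epochs_used = length(good),
    subject_id = block$subject_id, age_days = block$age_days,
    tone_id = block$tone_id, nativeness = block$nativeness,
    response_kind = block$response_kind,
    sampling_rate_hz = block$sampling_rate_hz
  ), class = "averaged_response")
}

#' Run one epoch block through a full extraction pipeline
#'
#' Filters every sweep (zero-phase), resamples to the target rate, flags
#' artifact sweeps, applies block QC and averages with baseline correction.
#'
#' @param block A raw `epoch_block`.
#' @param config A [pipeline_config()].
#' @return list(averaged, qc, bad_mask, block): the averaged response (NULL
#'   when nothing survived), the QC decision, the artifact mask, and the
#'   filtered/downsampled block with `qc_state` set to
#'   `"accepted"`/`"rejected"`.
#' @export
preprocess_block <- function(block, config) {
  fs <- block$sampling_rate_hz
  ep <- bandpass(block$epochs, config$band, fs, config$filter_order)
  if (fs != config$target_rate) {
    ep <- resample(ep, fs, config$target_rate)
  }
  time_ms <- epoch_time_axis(c(block$time_ms[1],
                               block$time_ms[1] +
                                 ncol(block$epochs) / fs * 1000),
                             config$target_rate)
  ds <- new_epoch_block(ep, time_ms, config$target_rate, block$polarity,
                        block$subject_id, block$age_days, block$tone_id,
                        block$nativeness, block$response_kind,
                        n_artifacts = block$n_artifacts_injected)
  # trim to the analysis epoch window if the raw sweeps were wider
  keep <- window_index(ds$time_ms, config$epoch_ms)
  ds$epochs <- ds$epochs[, keep, drop = FALSE]
  ds$time_ms <- ds$time_ms[keep]
  bad <- reject_artifacts(ds, config$reject_uv)
  averaged <- if (any(!bad)) {
    average_epochs(ds, bad, baseline_ms = config$baseline_ms,
                   cap = config$epoch_cap)
  } else NULL
  qc <- qc_block(bad, averaged, config)
  ds$qc_state <- if (qc$accept) "accepted" else "rejected"
  list(averaged = if (qc$accept) averaged else NULL,
       qc = qc, bad_mask = bad, block = ds)
}
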