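## Long-latency response metrics: P1 detection and LLR SNR.

#' Detect the P1 positivity
#'
#' The infant long-latency response is dominated by a broad positive
#' deflection (P1); it is located automatically as the maximum of the
#' averaged waveform across the post-stimulus search window. No smoothing is
#' applied before peak-picking; ties break to the earliest latency. An
#' argmax landing on a window edge is accepted but flagged.
#'
#' @param averaged An `averaged_response` with `response_kind = "llr"`.
#' @param search_window_ms Search window (ms), default 0-600.
#' @return list(latency_ms, amplitude_uv, at_edge).
#' @export
detect_p1 <- function(averaged, search_window_ms = c(0, 600)) {
  assert_that(identical(averaged$response_kind, "llr"),
              "detect_p1 expects a long-latency response")
  idx <- which(averaged$time_ms >= search_window_ms[1] &
               averaged$time_ms <= search_window_ms[2])
  assert_that(length(idx) > 0, "empty search window")
  w <- averaged$waveform[idx]
  k <- which.max(w) # first maximum on ties
  list(latency_ms = averaged$time_ms[idx[k]],
       amplitude_uv = w[k],
       at_edge = k == 1 || k == length(idx))
}

#' LLR signal-to-noise ratio
#'
#' Same dB contract as [snr_db()], with the long-latency windows: a
#' pre-stimulus interval of -100..0 ms and a post-stimulus interval of
#' 0..600 ms.
#'
#' @param averaged An `averaged_response`.
#' @return SNR in dB.
#' @export
llr_snr <- function(averaged) {
  snr_db(averaged$waveform, averaged$time_ms,
         pre_ms = c(-100, 0), post_ms = c(0, 600))
}

#' All LLR metrics for one preprocessed block
#'
#' @param pp Output of [preprocess_block()] with an accepted LLR block.
#' @return One-row data.frame: subject, age, tone, nativeness, P1 latency
#'   and amplitude, SNR, epochs used and edge flag.
#' @export
llr_block_metrics <- function(pp) {
  avg <- pp$averaged
  assert_that(!is.null(avg), "block was rejected by QC; no metrics")
  p1 <- detect_p1(avg)
  data.frame(
    subject_id = avg$subject_id, age_days = avg$age_days,
    tone = avg$tone_id, nativeness = avg$nativeness,
    n_epochs_used = avg$n_epochs_used,
    p1_latency_ms = p1$latency_ms, p1_amplitude_uv = p1$amplitude_uv,
    p1_at_edge = p1$at_edge,
    snr_db = llr_snr(avg),
    stringsAsFactors = FALSE
  )
}
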