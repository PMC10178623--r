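#' Lexical-tone stimulus definitions
#'
#' Three /ga/ syllables carrying lexical tones are used throughout: two
#' native Cantonese tones (rising tone 2, falling tone 4) and the non-native
#' Mandarin dipping tone 3. Fundamental-frequency (F0) ranges are
#' 182-278 Hz (/ga2/), 152-187 Hz (/ga4/) and 142-177 Hz (/ga3/), with Chao
#' contour numerals 25, 21 and 214. Stimuli are presented 1000 times per
#' block with a 500 ms interstimulus interval and a 674 ms
#' stimulus-onset asynchrony, in alternating polarity; the stimulus duration
#' is therefore 174 ms (SOA minus ISI).
#'
#' @return A data.frame with one row per tone: `tone_id`, `nativeness`,
#'   `chao_shape`, `f0_min`, `f0_max`.
#' @export
tone_table <- function() {
  data.frame(
    tone_id    = c("ga2", "ga4", "ga3"),
    nativeness = c("native", "native", "nonnative"),
    chao_shape = c("25", "21", "214"),
    f0_min     = c(182, 152, 142),
    f0_max     = c(278, 187, 177),
    stringsAsFactors = FALSE
  )
}

# presentation timing (ms) and default sweeps per block
STIM_ISI_MS <- 500
STIM_SOA_MS <- 674
STIM_DURATION_MS <- STIM_SOA_MS - STIM_ISI_MS # 174 ms
STIM_N_SWEEPS <- 1000L

# F0 trajectory for a Chao contour over the nominal range, sampled at
# `times_ms` within [0, duration]. "25" rises min -> max, "21" falls
# max -> min; "214" falls to the range minimum at 60% of the duration then
# rises to the range maximum, starting at the Chao-digit-2 level
# interpolated between the dip (digit 1) and the endpoint (digit 4).
chao_contour <- function(chao_shape, f0_min, f0_max, times_ms, duration_ms) {
  u <- times_ms / duration_ms
  u <- pmin(pmax(u, 0), 1)
  switch(chao_shape,
    "25" = f0_min + u * (f0_max - f0_min),
    "21" = f0_max - u * (f0_max - f0_min),
    "214" = {
      f0_start <- f0_min + (2 - 1) / (4 - 1) * (f0_max - f0_min)
      dip_u <- 0.6
      ifelse(u <= dip_u,
             f0_start + (u / dip_u) * (f0_min - f0_start),
             f0_min + ((u - dip_u) / (1 - dip_u)) * (f0_max - f0_min))
    },
    "flat" = rep((f0_min + f0_max) / 2, length(u)),
    stop("unknown Chao contour shape: ", chao_shape)
  )
}

#' Build a stimulus specification
#'
#' @param tone_id One of `"ga2"`, `"ga4"`, `"ga3"`, or `"custom"` together
#'   with `f0_start`/`f0_end` for control stimuli (a constant-F0 control is
#'   obtained with `f0_start == f0_end`).
#' @param sampling_rate Sampling rate in Hz for the contour/waveform grid.
#' @param f0_start,f0_end Custom endpoint frequencies (Hz); ignored for the
#'   three named tones.
#' @param n_sweeps Presentations per block.
#' @return An object of class `stimulus_spec` with the F0 contour sampled on
#'   the waveform grid, timing fields, and nativeness label.
#' @export
stimulus_spec <- function(tone_id, sampling_rate = 20000,
                          f0_start = NULL, f0_end = NULL,
                          n_sweeps = STIM_N_SWEEPS) {
  assert_that(is.character(tone_id) && length(tone_id) == 1,
              "tone_id must be a single string")
  tt <- tone_table()
  n <- round(STIM_DURATION_MS * sampling_rate / 1000)
  # inclusive grid so the contour endpoints sit exactly on the nominal bounds
  times <- seq(0, STIM_DURATION_MS, length.out = n)
  if (tone_id %in% tt$tone_id) {
    row <- tt[tt$tone_id == tone_id, ]
    contour <- chao_contour(row$chao_shape, row$f0_min, row$f0_max,
                            times, STIM_DURATION_MS)
    spec <- list(
      tone_id = tone_id, nativeness = row$nativeness,
      chao_shape = row$chao_shape,
      f0_start = contour[1], f0_end = contour[n],
      f0_min = row$f0_min, f0_max = row$f0_max
    )
  } else if (identical(tone_id, "custom")) {
    assert_that(!is.null(f0_start) && !is.null(f0_end),
                "custom stimuli need f0_start and f0_end")
    contour <- f0_start + times / STIM_DURATION_MS * (f0_end - f0_start)
    spec <- list(
      tone_id = "custom", nativeness = "nonnative", chao_shape = NA_character_,
      f0_start = f0_start, f0_end = f0_end,
      f0_min = min(f0_start, f0_end), f0_max = max(f0_start, f0_end)
    )
  } else {
    stop("unknown tone_id: '", tone_id,
         "' (expected ga2, ga4, ga3 or custom)", call. = FALSE)
  }
  spec$f0_contour <- contour
  spec$contour_times_ms <- times
  spec$duration_ms <- STIM_DURATION_MS
  spec$isi_ms <- STIM_ISI_MS
  spec$soa_ms <- STIM_SOA_MS
  spec$n_sweeps <- as.integer(n_sweeps)
  spec$sampling_rate <- sampling_rate
  class(spec) <- "stimulus_spec"
  spec
}

# harmonic amplitude rolloff used for both the stimulus and the simulated
# phase-locked response (F0 plus harmonics 2 and 3)
HARMONIC_AMPS <- c(1, 0.5, 0.25)

# instantaneous phase (cycles) of the F0 trajectory
contour_phase <- function(f0_contour, sampling_rate) {
  cumsum(f0_contour) / sampling_rate
}

#' Synthesize a lexical-tone stimulus waveform
#'
#' The pressure waveform is a harmonic complex (F0 plus harmonics 2-3 at
#' 6 dB/harmonic rolloff) whose instantaneous F0 follows the tone's Chao
#' contour across its nominal frequency range, over the 174 ms stimulus
#' duration.
#'
#' @inheritParams stimulus_spec
#' @return A `stimulus_spec` with an additional `waveform` element
#'   (unit peak amplitude) on the same grid as `f0_contour`.
#' @export
synthesize_stimulus <- function(tone_id, sampling_rate = 20000,
                                f0_start = NULL, f0_end = NULL,
                                n_sweeps = STIM_N_SWEEPS) {
  spec <- stimulus_spec(tone_id, sampling_rate, f0_start, f0_end, n_sweeps)
  f_high <- 3 * spec$f0_max
  assert_that(sampling_rate >= 4 * f_high,
              sprintf("sampling_rate must be >= 4x the highest harmonic (%g Hz)",
                      4 * f_high))
  ph <- contour_phase(spec$f0_contour, sampling_rate)
  w <- numeric(length(ph))
  for (h in seq_along(HARMONIC_AMPS)) {
    w <- w + HARMONIC_AMPS[h] * sin(2 * pi * h * ph)
  }
  spec$waveform <- w / max(abs(w))
  spec
}

#' Stimulus pitch contour on an analysis time grid
#'
#' @param spec A `stimulus_spec`.
#' @param step_ms Sampling step of the returned contour (ms).
#' @return A `pitch_contour` object (`times_ms`, `f0_hz`, `source`).
#' @export
stimulus_pitch_contour <- function(spec, step_ms = 5) {
  times <- seq(0, spec$duration_ms, by = step_ms)
  f0 <- stats::approx(spec$contour_times_ms, spec$f0_contour, xout = times,
                      rule = 2)$y
  structure(list(times_ms = times, f0_hz = f0, source = "stimulus"),
            class = "pitch_contour")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s (%s, Chao %s): F0 %g-%g Hz, %g ms, %d sweeps/block\n",
              x$tone_id, x$nativeness, x$chao_shape, x$f0_min, x$f0_max,
              x$duration_ms, x$n_sweeps))
  invisible(x)
}
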