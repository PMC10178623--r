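## Frequency-following response metrics.
##
## Four headline measures -- SNR, autocorrelogram pitch strength, and mean
## spectral power in the lower (120-260 Hz) and middle (260-750 Hz) bands --
## plus the intertrial-phase-coherence (ITPC) pitch contour and its tracking
## accuracy against the stimulus contour shifted 20 ms later in time.

# spectral band defaults (Hz)
FFR_LOW_BAND <- c(120, 260)
FFR_MID_BAND <- c(260, 750)

#' Signal-to-noise ratio in dB
#'
#' `10 * log10` of the ratio of mean-square power in the post-stimulus
#' window to mean-square power in the pre-stimulus window (equivalently
#' `20 * log10` of the RMS ratio).
#'
#' @param waveform Averaged waveform (uV).
#' @param time_ms Time axis (ms).
#' @param pre_ms,post_ms Half-open windows, both inside the epoch.
#' @return SNR in dB.
#' @export
snr_db <- function(waveform, time_ms, pre_ms = c(-50, 0),
                   post_ms = c(0, 225)) {
  pre_i <- window_index(time_ms, pre_ms)
  post_i <- window_index(time_ms, post_ms)
  assert_that(length(pre_i) > 0 && length(post_i) > 0,
              "SNR windows must lie inside the epoch")
  p_pre <- mean_square(waveform[pre_i])
  assert_that(p_pre > 0, "zero pre-stimulus power: SNR undefined")
  10 * log10(mean_square(waveform[post_i]) / p_pre)
}

#' Autocorrelogram pitch strength
#'
#' Normalized (biased, lag-0 = 1) autocorrelation of the waveform; the
#' pitch strength is the swing between the first local maximum of the
#' autocorrelogram within the F0 lag search range and the trough preceding
#' it (the minimum between lag 0 and the peak).
#'
#' @param waveform Averaged FFR waveform.
#' @param fs Sampling rate (Hz).
#' @param lag_range_ms Search range for the first peak; the default
#'   2.5-12.5 ms covers 80-400 Hz.
#' @return list(strength, peak_lag_ms, acf, lags_ms, found): `strength` is 0
#'   with `found = FALSE` when no local maximum lies in the range.
#' @export
pitch_strength <- function(waveform, fs, lag_range_ms = c(2.5, 12.5)) {
  n <- length(waveform)
  max_lag <- ceiling(lag_range_ms[2] * fs / 1000) + 1
  assert_that(n > 2 * max_lag, "waveform too short for the lag search range")
  x <- waveform - mean(waveform)
  # biased ACF via FFT
  m <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:(max_lag + 1)] / m
  ac <- ac / ac[1]
  lags_ms <- (0:max_lag) / fs * 1000
  in_range <- which(lags_ms >= lag_range_ms[1] & lags_ms <= lag_range_ms[2])
  k <- in_range[in_range > 1 & in_range < length(ac)]
  is_peak <- ac[k] > ac[k - 1] & ac[k] >= ac[k + 1]
  if (!any(is_peak)) {
    return(list(strength = 0, peak_lag_ms = NA_real_, acf = ac,
                lags_ms = lags_ms, found = FALSE))
  }
  pk <- k[which(is_peak)[1]]
  trough <- min(ac[2:pk])
  list(strength = ac[pk] - trough, peak_lag_ms = lags_ms[pk], acf = ac,
       lags_ms = lags_ms, found = TRUE)
}

#' Spectral band power of a waveform
#'
#' One-sided periodogram of the (optionally zero-padded) waveform, scaled so
#' that the `"sum"` aggregate over a partition of [0, Nyquist] equals the
#' time-domain mean square (Parseval). The default `"mean"` aggregate (mean
#' power per bin) makes bands of different widths comparable.
#'
#' @param waveform Post-stimulus portion of the averaged waveform (uV).
#' @param fs Sampling rate (Hz).
#' @param band `c(low, high)` in Hz; bins with `low <= f < high` are used
#'   (the Nyquist bin is included when `high >= fs/2`).
#' @param nfft Zero-padded spectrum length for stable band edges.
#' @param aggregate `"mean"` (default) or `"sum"` across in-band bins.
#' @return Band power in uV^2.
#' @export
band_power <- function(waveform, fs, band, nfft = 4096,
                       aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  assert_that(band[1] >= 0 && band[1] < band[2] && band[1] < fs / 2,
              "band must lie within [0, Nyquist)")
  n <- length(waveform)
  m <- max(nfft, n)
  X <- stats::fft(c(waveform, rep(0, m - n)))
  nb <- m %/% 2 + 1
  p <- Mod(X[1:nb])^2 / (n * m)
  # double interior bins to fold in negative frequencies
  interior <- 2:(nb - 1 + m %% 2)
  p[interior] <- 2 * p[interior]
  freq <- (0:(nb - 1)) * fs / m
  sel <- freq >= band[1] & freq < band[2]
  if (band[2] >= fs / 2) sel <- sel | seq_along(freq) == nb
  assert_that(any(sel), "no spectral bins fall inside the band")
  if (aggregate == "mean") mean(p[sel]) else sum(p[sel])
}

# --- intertrial phase coherence -------------------------------------------

#' Intertrial phase coherence (phase-locking factor) map
#'
#' Morlet-style time-frequency decomposition of every epoch; at each
#' (frequency, time) cell the complex coefficients are unit-normalized and
#' averaged across epochs, and the magnitude of that mean is the ITPC
#' (1 = perfect phase alignment; ~1/sqrt(n) for independent noise).
#' Wavelets are implemented as Gaussian frequency-domain kernels
#' (sd `f / n_cycles`), applied to each epoch's spectrum.
#'
#' @param block An `epoch_block` (typically the filtered, downsampled block
#'   from [preprocess_block()]).
#' @param freqs Analysis frequencies (Hz), strictly increasing; the default
#'   100-350 Hz in 2 Hz steps covers all stimulus F0 ranges with margin.
#' @param n_cycles Wavelet width in cycles; 12 cycles gives a frequency
#'   resolution (sd `f/12`, ~12-23 Hz over the F0 range) narrow enough for
#'   stable ridge extraction while keeping the temporal blur (~4-13 ms)
#'   small against the 174 ms stimulus.
#' @param bad_mask Optional logical mask of epochs to exclude.
#' @return An `itpc_map`: `values` (n_freq x n_time, in [0, 1]), `freq_hz`,
#'   `time_ms`, `n_epochs`.
#' @export
itpc <- function(block, freqs = seq(100, 350, by = 2), n_cycles = 12,
                 bad_mask = NULL) {
  epochs <- block$epochs
  if (!is.null(bad_mask)) epochs <- epochs[!bad_mask, , drop = FALSE]
  n_ep <- nrow(epochs)
  assert_that(n_ep >= 2, "ITPC requires at least 2 epochs")
  fs <- block$sampling_rate_hz
  ns <- ncol(epochs)
  ft <- stats::mvfft(t(epochs)) # ns x n_ep
  fax <- (seq_len(ns) - 1) * fs / ns # 0..fs grid (one-sided analytic kernel)
  vals <- matrix(0, nrow = length(freqs), ncol = ns)
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_f <- f / n_cycles
    # analytic wavelet: support on positive frequencies only
    kern <- ifelse(fax <= fs / 2, exp(-(fax - f)^2 / (2 * sigma_f^2)), 0)
    z <- stats::mvfft(ft * kern, inverse = TRUE) / ns
    mag <- Mod(z)
    mag[mag == 0] <- Inf # zero coefficient contributes a zero unit vector
    u <- z / mag
    vals[j, ] <- Mod(rowMeans(Re(u)) + 1i * rowMeans(Im(u)))
  }
  vals <- pmin(pmax(vals, 0), 1) # guard rounding at perfect coherence
  structure(list(values = vals, freq_hz = freqs, time_ms = block$time_ms,
                 n_epochs = n_ep), class = "itpc_map")
}

#' Extract the pitch contour from an ITPC map
#'
#' A sliding window is moved along the time axis; at each position the map
#' is averaged over the window (the default 5 ms window spans 1-2 map
#' columns -- the wavelet's own temporal envelope already smooths in time,
#' and longer boxes bias the ridge on frequency glides) and the contour
#' frequency is the ITPC-maximizing frequency within the search range,
#' refined by the coherence-weighted centroid within `refine_span_hz` of the
#' argmax (standard sub-grid ridge refinement).
#'
#' The contour support is `time_range` when given -- normally the neural-lag
#' shifted stimulus span, which is known in an evoked design. Otherwise
#' window positions whose peak coherence falls below `min_coherence_frac` of
#' the strongest position are discarded, so the contour covers only the
#' phase-locked portion of the epoch.
#'
#' @param map An `itpc_map`.
#' @param f0_search `c(low, high)` search range in Hz (inside the map grid).
#' @param window_ms Sliding window length (ms).
#' @param step_ms Contour sampling step (ms).
#' @param time_range Optional `c(first, last)` window centres (ms); the last
#'   centre is always included.
#' @param refine_span_hz Half-width of the centroid refinement span; 0
#'   disables refinement (pure grid argmax).
#' @param edge_ms Width of the support-edge zone whose ridge estimates are
#'   replaced by linear extrapolation of the adjacent clean segment. Within
#'   ~2 temporal standard deviations of the wavelet from either support
#'   edge, the wavelet integrates the chirp one-sidedly and drags the ridge
#'   toward interior frequencies; extrapolation through that zone removes
#'   the bias. 0 disables the correction.
#' @param min_coherence_frac Coherence gate used when `time_range` is NULL.
#' @return A `pitch_contour` (`times_ms`, `f0_hz`, `peak_itpc`,
#'   `source = "response"`).
#' @export
extract_pitch_contour <- function(map, f0_search = c(120, 300),
                                  window_ms = 5, step_ms = 5,
                                  time_range = NULL, refine_span_hz = 10,
                                  edge_ms = 15, min_coherence_frac = 0.5) {
  assert_that(max(map$values) > 0, "all-zero ITPC map")
  fi <- which(map$freq_hz >= f0_search[1] & map$freq_hz <= f0_search[2])
  assert_that(length(fi) > 1, "F0 search range outside the frequency grid")
  t0 <- map$time_ms[1]
  t1 <- map$time_ms[length(map$time_ms)]
  centres <- if (is.null(time_range)) {
    seq(t0, t1, by = step_ms)
  } else {
    unique(c(seq(max(time_range[1], t0), min(time_range[2], t1),
                 by = step_ms), min(time_range[2], t1)))
  }
  half <- window_ms / 2
  freqs <- map$freq_hz[fi]
  peak_f <- numeric(length(centres))
  peak_v <- numeric(length(centres))
  for (i in seq_along(centres)) {
    ci <- which(map$time_ms >= centres[i] - half &
                map$time_ms <= centres[i] + half)
    if (length(ci) == 0) ci <- which.min(abs(map$time_ms - centres[i]))
    prof <- rowMeans(map$values[fi, ci, drop = FALSE])
    k <- which.max(prof)
    peak_v[i] <- prof[k]
    if (refine_span_hz > 0) {
      sel <- abs(freqs - freqs[k]) <= refine_span_hz
      w <- pmax(prof[sel] - min(prof[sel]), 0)
      peak_f[i] <- if (sum(w) > 0) sum(freqs[sel] * w) / sum(w) else freqs[k]
    } else {
      peak_f[i] <- freqs[k]
    }
  }
  keep <- if (is.null(time_range)) {
    peak_v >= min_coherence_frac * max(peak_v)
  } else rep(TRUE, length(centres))
  times <- centres[keep]
  f0 <- peak_f[keep]
  if (edge_ms > 0 && length(times) >= 8) {
    f0 <- correct_ridge_edges(times, f0, edge_ms,
                              clamp = range(map$freq_hz[fi]))
  }
  structure(list(times_ms = times, f0_hz = f0,
                 peak_itpc = peak_v[keep], source = "response"),
            class = "pitch_contour")
}

# Replace ridge estimates within `edge_ms` of the support edges by linear
# extrapolation of the neighbouring 2*edge_ms segment (clamped to the
# analysed frequency range).
correct_ridge_edges <- function(times, f0, edge_ms, clamp) {
  t0 <- min(times); t1 <- max(times)
  fix_zone <- function(zone, ref) {
    if (sum(ref) >= 4 && any(zone)) {
      fit <- stats::lm(f ~ t, data = data.frame(t = times[ref], f = f0[ref]))
      pred <- stats::predict(fit, data.frame(t = times[zone]))
      f0[zone] <<- pmin(pmax(pred, clamp[1]), clamp[2])
    }
  }
  fix_zone(times < t0 + edge_ms,
           times >= t0 + edge_ms & times < t0 + 3 * edge_ms)
  fix_zone(times > t1 - edge_ms,
           times <= t1 - edge_ms & times > t1 - 3 * edge_ms)
  f0
}

#' Pitch-tracking accuracy against the stimulus contour
#'
#' Pearson correlation between the response pitch contour and the stimulus
#' pitch contour shifted `lag_ms` later in time, evaluated on the
#' overlapping support (the stimulus contour is interpolated onto the
#' response contour's time base).
#'
#' @param response A `pitch_contour` from [extract_pitch_contour()].
#' @param stimulus A `pitch_contour` from [stimulus_pitch_contour()].
#' @param lag_ms Neural lag applied to the stimulus contour (default 20 ms).
#' @return list(r, r2, n, degenerate): when either contour is constant on
#'   the overlap the correlation is undefined and `r2` is reported as 0 with
#'   `degenerate = TRUE`.
#' @export
tracking_accuracy <- function(response, stimulus, lag_ms = 20) {
  st <- stimulus$times_ms + lag_ms
  lo <- max(min(st), min(response$times_ms))
  hi <- min(max(st), max(response$times_ms))
  sel <- response$times_ms >= lo & response$times_ms <= hi
  assert_that(sum(sel) >= 3, "contour overlap shorter than 3 points")
  rf <- response$f0_hz[sel]
  sf <- stats::approx(st, stimulus$f0_hz, xout = response$times_ms[sel])$y
  if (stats::sd(rf) == 0 || stats::sd(sf) == 0) {
    return(list(r = NA_real_, r2 = 0, n = sum(sel), degenerate = TRUE))
  }
  r <- stats::cor(rf, sf)
  list(r = r, r2 = r^2, n = sum(sel), degenerate = FALSE)
}

#' All FFR metrics for one preprocessed block
#'
#' @param pp Output of [preprocess_block()] with an accepted FFR block.
#' @param stimulus Optional `stimulus_spec`; when given, the ITPC pitch
#'   contour and tracking accuracy are computed.
#' @param config Optional list overriding metric parameters (`pre_ms`,
#'   `post_ms`, `low_band`, `mid_band`, `itpc_freqs`, `f0_search`,
#'   `window_ms`, `step_ms`, `lag_ms`).
#' @return One-row data.frame of FFR metrics.
#' @export
ffr_block_metrics <- function(pp, stimulus = NULL, config = list()) {
  avg <- pp$averaged
  assert_that(!is.null(avg), "block was rejected by QC; no metrics")
  cfg <- utils::modifyList(list(
    pre_ms = c(-50, 0), post_ms = c(0, 225),
    low_band = FFR_LOW_BAND, mid_band = FFR_MID_BAND,
    itpc_freqs = seq(100, 350, by = 2), f0_search = c(120, 300),
    window_ms = 5, step_ms = 5, lag_ms = 20), config)
  fs <- avg$sampling_rate_hz
  post <- avg$waveform[window_index(avg$time_ms, cfg$post_ms)]
  ps <- pitch_strength(avg$waveform, fs)
  post_t <- avg$time_ms[window_index(avg$time_ms, cfg$post_ms)]
  pk <- which.max(abs(post))
  out <- data.frame(
    subject_id = avg$subject_id, age_days = avg$age_days,
    tone = avg$tone_id, nativeness = avg$nativeness,
    n_epochs_used = avg$n_epochs_used,
    snr_db = snr_db(avg$waveform, avg$time_ms, cfg$pre_ms, cfg$post_ms),
    pitch_strength = ps$strength,
    low_power = band_power(post, fs, cfg$low_band),
    mid_power = band_power(post, fs, cfg$mid_band),
    peak_amplitude_uv = abs(post[pk]),
    peak_latency_ms = post_t[pk],
    tracking_r = NA_real_, tracking_r2 = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(stimulus)) {
    m <- itpc(pp$block, freqs = cfg$itpc_freqs, bad_mask = pp$bad_mask)
    contour <- extract_pitch_contour(m, cfg$f0_search, cfg$window_ms,
                                     cfg$step_ms,
                                     time_range = cfg$lag_ms +
                                       c(0, stimulus$duration_ms))
    tr <- tracking_accuracy(contour, stimulus_pitch_contour(stimulus,
                                                            cfg$step_ms),
                            lag_ms = cfg$lag_ms)
    out$tracking_r <- tr$r
    out$tracking_r2 <- tr$r2
  }
  out
}
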