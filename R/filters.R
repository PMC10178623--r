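## Zero-phase Butterworth filtering and anti-aliased resampling.
##
## Filters are applied as zero-phase magnitude responses in the frequency
## domain (with reflection padding), equivalent in magnitude to
## forward-backward ("filtfilt") application of the corresponding
## Butterworth design: the applied gain is |H(f)|^2 where |H| is the
## magnitude of an order-`order` Butterworth band-pass (analog prototype,
## standard low-pass -> band-pass transform). Zero phase avoids any latency
## bias in P1 and FFR lag estimates.

# squared magnitude of an order-n Butterworth band-pass at frequencies f
butter_bandpass_mag2 <- function(f, band, order) {
  f0sq <- band[1] * band[2]
  bw <- band[2] - band[1]
  u <- ifelse(f <= 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + u^(2 * order))
}

butter_lowpass_mag2 <- function(f, cutoff, order) {
  1 / (1 + (f / cutoff)^(2 * order))
}

# apply a frequency-domain gain (zero phase) to rows of x with reflection
# padding; gain_fun(freq_hz) -> multiplicative gain on the two-sided axis
apply_fft_gain <- function(x, fs, gain_fun, chunk = 256L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  pad <- n # full reflection each side
  m <- n + 2 * pad
  freq <- (seq_len(m) - 1) * fs / m
  freq <- pmin(freq, fs - freq)
  g <- gain_fun(freq)
  out <- matrix(0, nrow = nrow(x), ncol = n)
  idx <- seq_len(nrow(x))
  for (start in seq(1, nrow(x), by = chunk)) {
    rows <- idx[start:min(start + chunk - 1, nrow(x))]
    block <- x[rows, , drop = FALSE]
    padded <- cbind(block[, pad:1, drop = FALSE], block,
                    block[, n:(n - pad + 1), drop = FALSE])
    ft <- stats::mvfft(t(padded))
    ft <- ft * g
    filt <- Re(stats::mvfft(ft, inverse = TRUE)) / m
    out[rows, ] <- t(filt)[, (pad + 1):(pad + n), drop = FALSE]
  }
  if (vec) drop(out) else out
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param x Numeric vector, or matrix with one signal per row.
#' @param band `c(low, high)` cutoff frequencies in Hz, inside (0, Nyquist).
#' @param fs Sampling rate (Hz).
#' @param order Design order of the underlying Butterworth band-pass (even).
#' @return Filtered signal(s), same shape as `x`. Pass-band gain is ~1 and
#'   stop bands are strongly attenuated; the filter is exactly zero-phase.
#' @export
bandpass <- function(x, band, fs, order = 8) {
  assert_that(length(band) == 2 && band[1] > 0 && band[1] < band[2],
              "band must be c(low, high) with 0 < low < high")
  assert_that(band[2] < fs / 2, "upper band edge must be below Nyquist")
  assert_that(order %% 2 == 0, "filter order must be even")
  apply_fft_gain(x, fs, function(f) butter_bandpass_mag2(f, band, order))
}

#' Zero-phase Butterworth low-pass filter
#'
#' @inheritParams bandpass
#' @param cutoff Cutoff frequency in Hz (below Nyquist).
#' @export
lowpass <- function(x, cutoff, fs, order = 4) {
  assert_that(cutoff > 0 && cutoff < fs / 2, "cutoff must be in (0, Nyquist)")
  apply_fft_gain(x, fs, function(f) butter_lowpass_mag2(f, cutoff, order))
}

#' Anti-aliased resampling (Fourier method)
#'
#' Resamples to `round(n * rate_out / rate_in)` samples by spectral
#' truncation (removing content above the new Nyquist), preserving duration.
#'
#' @param x Numeric vector or matrix (signals in rows).
#' @param rate_in,rate_out Sampling rates in Hz, both > 0,
#'   `rate_out <= rate_in`.
#' @return Resampled signal(s).
#' @export
resample <- function(x, rate_in, rate_out) {
  assert_that(rate_in > 0 && rate_out > 0, "rates must be positive")
  assert_that(rate_out <= rate_in, "rate_out must be <= rate_in")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  n_out <- round(n * rate_out / rate_in)
  out <- resample_n_rows(x, n_out)
  if (vec) drop(out) else out
}

# Fourier resampling of rows to exactly n_out samples. Bins share physical
# frequencies because the duration is preserved; content above the new
# Nyquist is discarded (anti-aliasing).
resample_n_rows <- function(x, n_out) {
  n <- ncol(x)
  if (n_out == n) return(x)
  ft <- stats::mvfft(t(x)) # n x nrow
  keep <- min(n, n_out)
  half <- keep %/% 2
  y <- matrix(0 + 0i, nrow = n_out, ncol = nrow(x))
  if (keep %% 2 == 1) {
    y[seq_len(half + 1), ] <- ft[seq_len(half + 1), , drop = FALSE]
    if (half > 0) {
      neg <- seq_len(half)
      y[n_out - neg + 1, ] <- ft[n - neg + 1, , drop = FALSE]
    }
  } else if (n_out < n) {
    # downsampling to even length: output Nyquist bin collects its aliased
    # conjugate pair and must be real
    y[seq_len(half), ] <- ft[seq_len(half), , drop = FALSE]
    y[half + 1, ] <- Re(ft[half + 1, , drop = FALSE])
    neg <- seq_len(half - 1)
    if (length(neg) > 0) y[n_out - neg + 1, ] <- ft[n - neg + 1, , drop = FALSE]
  } else {
    # upsampling from even length: split the input Nyquist bin symmetrically
    y[seq_len(half), ] <- ft[seq_len(half), , drop = FALSE]
    nyq <- ft[half + 1, , drop = FALSE]
    y[half + 1, ] <- nyq / 2
    y[n_out - half + 1, ] <- Conj(nyq) / 2
    neg <- seq_len(half - 1)
    if (length(neg) > 0) y[n_out - neg + 1, ] <- ft[n - neg + 1, , drop = FALSE]
  }
  t(Re(stats::mvfft(y, inverse = TRUE))) / n
}
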