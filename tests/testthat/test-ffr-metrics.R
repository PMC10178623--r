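test_that("SNR follows its closed forms and scaling laws", {
  fs <- 3000
  t <- -50 + (0:824) / 3 # ms
  pre <- t < 0
  w <- rnorm(825)
  w_eq <- w
  # equal pre/post mean-square power -> 0 dB
  post <- rep_len(w[pre], sum(!pre))
  w_eq[!pre] <- post * sqrt(mean(w[pre]^2) / mean(post^2))
  expect_equal(snr_db(w_eq, t), 0, tolerance = 1e-10)
  # post exactly 10x the pre shape -> 20 dB
  w10 <- w_eq
  w10[!pre] <- 10 * w_eq[!pre]
  expect_equal(snr_db(w10, t), 20, tolerance = 1e-10)
  # global scaling leaves SNR unchanged; post-only scaling adds 20 log10(c)
  expect_equal(snr_db(3.7 * w, t), snr_db(w, t), tolerance = 1e-10)
  wc <- w; wc[!pre] <- 2 * wc[!pre]
  expect_equal(snr_db(wc, t) - snr_db(w, t), 20 * log10(2),
               tolerance = 1e-10)
  expect_error(snr_db(c(rep(0, 150), rnorm(675)), t), "zero pre-stimulus")
})

test_that("generator blocks land within 1 dB of the analytic SNR", {
  # noise-only pre-window vs signal+noise post-window of the averaged block
  prof <- subject_profile(noise_sd = 3, artifact_rate = 0,
                          ffr_gain_intercept = 1, ffr_gain_slope_per_day = 0)
  stim <- synthesize_stimulus("ga2")
  snrs <- vapply(1:4, function(s) {
    blk <- generate_ffr_block(prof, stim, seed = 20 + s, n_sweeps = 400)
    pp <- preprocess_block(blk, pipeline_config("ffr"))
    snr_db(pp$averaged$waveform, pp$averaged$time_ms)
  }, numeric(1))
  # analytic: post = signal + residual noise, pre = residual noise
  blk0 <- generate_ffr_block(quiet_profile(ffr_gain_intercept = 1,
                                           ffr_gain_slope_per_day = 0),
                             stim, seed = 1, n_sweeps = 2)
  pp0 <- preprocess_block(blk0, pipeline_config("ffr"))
  p_sig <- mean(pp0$averaged$waveform[pp0$averaged$time_ms >= 0]^2)
  # residual noise variance in the average: estimate from one noise-only fit
  prof_n <- subject_profile(noise_sd = 3, artifact_rate = 0, ffr_amp_uv = 0,
                            ffr_carrier_uv = 0)
  blkn <- generate_ffr_block(prof_n, stim, seed = 31, n_sweeps = 400)
  ppn <- preprocess_block(blkn, pipeline_config("ffr"))
  p_noise <- mean(ppn$averaged$waveform^2)
  expected <- 10 * log10((p_sig + p_noise) / p_noise)
  expect_equal(mean(snrs), expected, tolerance = 1)
})

test_that("pitch strength tracks periodicity salience", {
  fs <- 3000
  x <- sin(2 * pi * 200 * (0:824) / fs)
  ps <- pitch_strength(x, fs)
  expect_true(ps$found)
  expect_equal(ps$peak_lag_ms, 5, tolerance = 0.4) # 1/200 Hz
  expect_gt(ps$strength, 1.7) # ACF swing of a sinusoid approaches 2
  expect_lt(ps$strength, 2)
  # white noise: near-zero strength (median over seeds)
  null_strength <- vapply(1:20, function(s) {
    set.seed(s)
    pitch_strength(rnorm(825), fs)$strength
  }, numeric(1))
  expect_lt(stats::median(null_strength), 0.25)
  # decreasing SNR -> non-increasing strength in expectation
  strengths <- vapply(c(0, 0.5, 2, 8), function(sd_) {
    mean(vapply(1:8, function(s) {
      set.seed(s)
      pitch_strength(x + rnorm(825, 0, sd_), fs)$strength
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(strengths) < 0))
  # no local maximum in the lag range -> strength 0 with a flag
  slow <- sin(2 * pi * 40 * (0:824) / fs)
  ps0 <- pitch_strength(slow, fs)
  expect_false(ps0$found)
  expect_equal(ps0$strength, 0)
  expect_error(pitch_strength(rnorm(50), fs), "too short")
})

test_that("band power respects spectral support and Parseval", {
  fs <- 3000
  x200 <- sin(2 * pi * 200 * (0:824) / fs)
  expect_gt(band_power(x200, fs, c(120, 260)),
            1e3 * band_power(x200, fs, c(260, 750)))
  # partition of [0, Nyquist] sums (aggregate = "sum") to the mean square
  y <- rnorm(825)
  parts <- list(c(0, 120), c(120, 260), c(260, 750), c(750, 1500))
  total <- sum(vapply(parts, function(b) band_power(y, fs, b,
                                                    aggregate = "sum"),
                      numeric(1)))
  expect_equal(total, mean(y^2), tolerance = 1e-6)
  # equal-amplitude 200+400+600 complex: the mid band holds two of the
  # three components -> twice the low band's summed power
  x3 <- x200 + sin(2 * pi * 400 * (0:824) / fs) +
    sin(2 * pi * 600 * (0:824) / fs)
  expect_equal(band_power(x3, fs, c(260, 750), aggregate = "sum") /
                 band_power(x3, fs, c(120, 260), aggregate = "sum"),
               2, tolerance = 0.05)
  expect_error(band_power(rnorm(8), fs, c(400, 401), nfft = 8), "bins")
})

test_that("ITPC is 1 for identical epochs, ~Rayleigh null for noise, and bounded", {
  fs <- 3000
  tmpl <- sin(2 * pi * 220 * (0:299) / fs)
  same <- matrix_block(matrix(rep(tmpl, each = 10), nrow = 10), t0_ms = 0)
  m1 <- itpc(same, freqs = seq(150, 300, 10))
  expect_true(all(m1$values >= 0 & m1$values <= 1))
  expect_true(all(m1$values > 0.999)) # perfect phase alignment
  # per-epoch amplitude rescaling leaves ITPC unchanged (phase statistic)
  scaled <- same
  scaled$epochs <- same$epochs * seq(0.1, 5, length.out = 10)
  expect_equal(itpc(scaled, freqs = seq(150, 300, 10))$values, m1$values,
               tolerance = 1e-9)
  # independent noise: mean ITPC ~ sqrt(pi / (4 n))
  set.seed(8)
  noise <- matrix_block(matrix(rnorm(100 * 300), nrow = 100), t0_ms = 0)
  m0 <- itpc(noise, freqs = seq(120, 320, 20))
  expect_equal(mean(m0$values), sqrt(pi / (4 * 100)), tolerance = 0.15)
  expect_error(itpc(matrix_block(matrix(rnorm(300), 1))), "2 epochs")
})

test_that("phase-locked components produce an ITPC ridge at their frequency", {
  fx <- tracked_block("ga2")
  ridge_col <- which.min(abs(fx$map$time_ms - 100)) # mid-response
  f_at_peak <- fx$map$freq_hz[which.max(fx$map$values[, ridge_col])]
  f_true <- 182 + (100 - 20) / 174 * 96 # contour at 80 ms post-onset
  expect_lt(abs(f_at_peak - f_true), 12)
})

test_that("the pitch tracker recovers contours and is shift-equivariant", {
  # constant-F0 block -> flat contour at the F0
  flat_ctr <- function(f0) {
    prof <- subject_profile(noise_sd = 0.5, artifact_rate = 0)
    stim <- synthesize_stimulus("custom", f0_start = f0, f0_end = f0)
    blk <- generate_ffr_block(prof, stim, seed = 6, n_sweeps = 150)
    pp <- preprocess_block(blk, pipeline_config("ffr"))
    extract_pitch_contour(itpc(pp$block, bad_mask = pp$bad_mask),
                          time_range = c(20, 194))$f0_hz
  }
  c200 <- flat_ctr(200)
  expect_lt(max(abs(c200 - 200)), 5)
  # +10 Hz generator shift moves the contour by +10 Hz
  c210 <- flat_ctr(210)
  expect_equal(mean(c210) - mean(c200), 10, tolerance = 3)
  # falling tone: contour non-increasing within tolerance of the refinement
  g4 <- tracked_block("ga4")
  expect_true(all(diff(g4$contour$f0_hz) <= 4))
  expect_error(extract_pitch_contour(
    structure(list(values = matrix(0, 3, 3), freq_hz = 1:3, time_ms = 1:3),
              class = "itpc_map")), "all-zero")
})

test_that("tracking accuracy behaves on identity, degenerate and short input", {
  stim <- stimulus_pitch_contour(stimulus_spec("ga2"), step_ms = 5)
  shifted <- structure(list(times_ms = stim$times_ms + 20, f0_hz = stim$f0_hz,
                            source = "response"), class = "pitch_contour")
  tr <- tracking_accuracy(shifted, stim, lag_ms = 20)
  expect_equal(tr$r2, 1, tolerance = 1e-12)
  const <- structure(list(times_ms = stim$times_ms + 20,
                          f0_hz = rep(200, length(stim$times_ms)),
                          source = "response"), class = "pitch_contour")
  trd <- tracking_accuracy(const, stim, lag_ms = 20)
  expect_true(trd$degenerate)
  expect_equal(trd$r2, 0)
  short <- structure(list(times_ms = c(20, 25), f0_hz = c(180, 190),
                          source = "response"), class = "pitch_contour")
  expect_error(tracking_accuracy(short, stim), "overlap")
})

test_that("noise-free blocks track all three tones with r2 >= 0.99", {
  for (tone in c("ga2", "ga4", "ga3")) {
    fx <- tracked_block(tone)
    tr <- tracking_accuracy(fx$contour, stimulus_pitch_contour(fx$stim),
                            lag_ms = 20)
    expect_gt(tr$r2, 0.99)
  }
})
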