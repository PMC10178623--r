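test_that("band-pass filter keeps the pass band and kills the stop band", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs)
  mid <- 2000:8000 # avoid edges
  x200 <- sin(2 * pi * 200 * t)
  y200 <- bandpass(x200, c(80, 1500), fs, 8)
  expect_equal(stats::sd(y200[mid]) / stats::sd(x200[mid]), 1,
               tolerance = 0.01)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(x10, c(80, 1500), fs, 8)
  atten_db <- 20 * log10(stats::sd(y10[mid]) / stats::sd(x10[mid]))
  expect_lt(atten_db, -40)
  # DC offset through the long-latency band is removed
  dc <- bandpass(rep(2, 14000), c(0.1, 30), fs, 4)
  expect_lt(abs(mean(dc)), 1e-9)
})

test_that("filter preconditions are validated", {
  expect_error(bandpass(rnorm(100), c(80, 12000), 20000, 8), "Nyquist")
  expect_error(bandpass(rnorm(100), c(80, 1500), 20000, 7), "even")
  expect_error(bandpass(rnorm(100), c(-1, 50), 20000, 8), "band")
})

test_that("resampling preserves duration, length arithmetic and amplitude", {
  fs <- 20000
  t <- (0:5499) / fs
  x <- sin(2 * pi * 300 * t)
  y <- resample(x, 20000, 3000)
  expect_equal(length(y), round(length(x) * 3 / 20)) # 825
  # RMS amplitude preserved (the peak may fall between samples)
  expect_equal(stats::sd(y[100:700]) * sqrt(2), 1, tolerance = 0.01)
  # a 1.4 kHz tone (below the new 1.5 kHz Nyquist) survives with bounded
  # distortion: its spectral peak stays at 1.4 kHz and keeps its amplitude
  x14 <- sin(2 * pi * 1400 * t)
  y14 <- resample(x14, 20000, 3000)
  sp <- Mod(stats::fft(y14))[1:412]
  fpk <- (which.max(sp) - 1) / length(y14) * 3000
  expect_lt(abs(fpk - 1400), 4)
  expect_equal(2 * max(sp) / length(y14), 1, tolerance = 0.05)
  expect_error(resample(x, 3000, 20000), "rate_out")
  expect_error(resample(x, -1, -2), "positive")
})

test_that("epoch extraction follows the half-open window arithmetic", {
  fs <- 3000
  x <- rnorm(10000)
  onsets <- c(500, 2000, 5000)
  blk <- extract_epochs(x, onsets, c(-50, 225), fs)
  expect_equal(ncol(blk$epochs), 825) # (225 - (-50)) ms x 3 samples/ms
  expect_equal(nrow(blk$epochs), 3)
  # a single well-padded onset reproduces the sliced signal
  expect_equal(blk$epochs[2, ], x[(2000 - 150):(2000 + 674)])
  llr <- extract_epochs(x, 2000, c(-100, 600), fs, response_kind = "llr")
  expect_equal(ncol(llr$epochs), 2100) # (600 + 100) ms x 3
  # onsets too close to the edge are dropped with a log message
  expect_message(b2 <- extract_epochs(x, c(10, 2000), c(-50, 225), fs),
                 "dropped")
  expect_equal(nrow(b2$epochs), 1)
  expect_equal(attr(b2, "dropped"), 1L)
})

test_that("artifact rejection flags epochs crossing the threshold", {
  ep <- matrix(0, nrow = 5, ncol = 100)
  blk <- matrix_block(ep)
  expect_equal(sum(reject_artifacts(blk, 25)), 0)
  ep[3, 40] <- 26
  expect_equal(which(reject_artifacts(matrix_block(ep), 25)), 3L)
  ep[3, 40] <- 25 # exactly at threshold: not over
  expect_equal(sum(reject_artifacts(matrix_block(ep), 25)), 0)
  expect_error(reject_artifacts(blk, -5), "threshold")
})

test_that("generator artifact counts are recovered by rejection", {
  prof <- subject_profile(noise_sd = 0.5, artifact_rate = 0.05)
  stim <- synthesize_stimulus("ga2")
  blk <- generate_ffr_block(prof, stim, seed = 9, n_sweeps = 200,
                            artifact_placement = "first")
  bad <- reject_artifacts(blk, 25)
  expect_equal(sum(bad), 10) # round(0.05 * 200)
  # retained epochs = n - k for k under the block threshold
  pp <- preprocess_block(blk, pipeline_config("ffr"))
  expect_equal(pp$qc$n_good, 190)
})

test_that("block QC applies the >10% and 0.7 uV rules", {
  cfg <- pipeline_config("ffr")
  avg_ok <- make_avg(rep(0.1, 825), t0_ms = -50, kind = "ffr")
  qc <- qc_block(rep(c(TRUE, FALSE), c(100, 900)), avg_ok, cfg)
  expect_true(qc$accept)
  expect_equal(qc$n_good, 900)
  qc2 <- qc_block(rep(c(TRUE, FALSE), c(101, 899)), avg_ok, cfg)
  expect_false(qc2$accept)
  expect_match(qc2$reason, "exceed")
  avg_big <- make_avg(c(rep(0.1, 824), 0.8), t0_ms = -50, kind = "ffr")
  qc3 <- qc_block(rep(FALSE, 1000), avg_big, cfg)
  expect_false(qc3$accept)
  expect_match(qc3$reason, "stimulus-artifact")
  # decisions are pure: same inputs, same outputs
  expect_identical(qc, qc_block(rep(c(TRUE, FALSE), c(100, 900)), avg_ok, cfg))
})

test_that("averaging caps at the first good epochs and baseline-corrects", {
  ep <- matrix(rnorm(320 * 60), nrow = 320)
  blk <- matrix_block(ep, fs = 200, t0_ms = -100, kind = "llr")
  avg <- average_epochs(blk, cap = 300, baseline_ms = c(-100, 0))
  expect_equal(avg$n_epochs_used, 300)
  expect_equal(avg$waveform, colMeans(ep[1:300, ]) -
                 mean(colMeans(ep[1:300, ])[blk$time_ms < 0]))
  # the cap takes the FIRST good epochs in recording order
  bad <- rep(FALSE, 320); bad[1:10] <- TRUE
  avg2 <- average_epochs(blk, bad, cap = 300)
  expect_equal(avg2$waveform, colMeans(ep[11:310, ]))
  # identical epochs average to any single epoch
  same <- matrix_block(matrix(rep(sin(1:60), each = 4), nrow = 4), fs = 200)
  expect_equal(average_epochs(same)$waveform, sin(1:60))
  expect_error(average_epochs(blk, rep(TRUE, 320)), "good epochs")
})

test_that("baseline window mean of averaged responses is numerically zero", {
  prof <- subject_profile(noise_sd = 1, artifact_rate = 0)
  stim <- synthesize_stimulus("ga3")
  blk <- generate_ffr_block(prof, stim, seed = 4, n_sweeps = 30)
  pp <- preprocess_block(blk, pipeline_config("ffr"))
  b <- pp$averaged$waveform[pp$averaged$time_ms < 0]
  expect_lt(abs(mean(b)), 1e-9)
})

test_that("filtering and averaging commute (linearity)", {
  ep <- matrix(rnorm(6 * 400), nrow = 6)
  f_then_a <- colMeans(bandpass(ep, c(80, 1400), 3000, 8))
  a_then_f <- bandpass(colMeans(ep), c(80, 1400), 3000, 8)
  expect_equal(f_then_a, a_then_f, tolerance = 1e-10)
})

test_that("averaging noise shrinks as 1/sqrt(n)", {
  tmpl <- sin(2 * pi * (1:300) / 25)
  rmse <- function(n, seed) {
    set.seed(seed)
    ep <- matrix(rep(tmpl, each = n), nrow = n) + rnorm(n * 300)
    sqrt(mean((colMeans(ep) - tmpl)^2))
  }
  ratios <- vapply(1:5, function(s) rmse(100, s) / rmse(400, s + 50),
                   numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.25)
})
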