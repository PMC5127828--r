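test_that("resampling preserves rate, length and spectral content", {
  sig256 <- make_signal(matrix(rnorm(2560 * 2), ncol = 2), fs = 256)
  expect_identical(resample_to_256(sig256), sig256)

  sig128 <- make_signal(matrix(rnorm(1280 * 2), ncol = 2), fs = 128)
  out <- resample_to_256(sig128)
  expect_equal(out$fs, 256)
  expect_equal(nrow(out$data), 2560)

  t500 <- seq_len(5000) / 500
  sin500 <- make_signal(sin(2 * pi * 10 * t500), fs = 500)
  res <- resample_to_256(sin500)
  expect_lt(abs(sine_amplitude(drop(res$data), 10, 256) - 1), 0.01)

  expect_error(resample_to_256(make_signal(rnorm(100), fs = 200)),
               "sampling rate")
})

test_that("band-pass filter suppresses DC, passes 10 Hz, rejects 60 Hz", {
  fs <- 256
  t <- seq_len(20 * fs) / fs
  trim <- (4 * fs):(16 * fs)

  dc <- bandpass_filter(make_signal(rep(5, length(t)), fs = fs))
  expect_lt(mean(abs(dc$data[trim, 1])), 0.05)

  s10 <- bandpass_filter(make_signal(sin(2 * pi * 10 * t), fs = fs))
  expect_lt(abs(sine_amplitude(s10$data[, 1], 10, fs, trim_s = 4) - 1), 0.01)

  s60 <- bandpass_filter(make_signal(sin(2 * pi * 60 * t), fs = fs))
  expect_lt(sine_amplitude(s60$data[, 1], 60, fs, trim_s = 4), 0.1)

  expect_error(bandpass_filter(make_signal(rnorm(100), fs = fs)), "shorter")
})

test_that("least-squares FIR design approximates the desired response", {
  h <- fir_ls(128, c(0, 20, 20, 30, 30, 64), c(1, 1, 1, 0, 0, 0), fs = 128)
  expect_length(h, 129)
  expect_equal(h, rev(h))               # linear phase: symmetric taps
  H <- function(f) abs(sum(h * exp(-2i * pi * f / 128 * (seq_along(h) - 1))))
  expect_lt(abs(H(10) - 1), 0.01)
  expect_lt(H(50), 0.01)
  expect_error(fir_ls(127, c(0, 64), c(1, 1), 128), "even")
})

test_that("epoch segmentation count follows the overlap arithmetic", {
  mk <- function(dur) make_signal(matrix(0, dur * 256, 2), fs = 256)
  expect_equal(dim(segment_epochs(mk(335))$epochs)[1], 334)
  expect_equal(dim(segment_epochs(mk(2))$epochs)[1], 1)
  expect_equal(dim(segment_epochs(mk(10))$epochs)[1], 9)
  expect_error(segment_epochs(mk(1)), "shorter")
  # epochs tile the signal left to right with the requested overlap
  sig <- make_signal(matrix(seq_len(256 * 4), ncol = 1), fs = 256)
  ep <- segment_epochs(sig)
  expect_equal(ep$epochs[2, , 1], sig$data[257:768, 1])
})

test_that("epoch spectra satisfy the Parseval convention on the 0.5 Hz grid", {
  set.seed(1)
  ep <- matrix(rnorm(512 * 3), 512, 3)
  sp <- epoch_spectrum(ep, full = TRUE)
  v_time <- apply(ep, 2, function(x) mean(x^2) - mean(x)^2)
  expect_lt(max(abs(colSums(sp$power) - v_time) / v_time), 1e-10)

  band <- epoch_spectrum(ep)
  expect_equal(nrow(band$power), 100)
  expect_equal(band$freq, seq(0.5, 50, by = 0.5))

  t <- seq_len(512) / 256
  pure <- epoch_spectrum(matrix(sin(2 * pi * 10 * t), ncol = 1))
  expect_equal(pure$freq[which.max(pure$power[, 1])], 10)

  expect_error(epoch_spectrum(matrix(0, 100, 1)), "2 s")
})

test_that("spectrum averaging is an arithmetic mean with truncation", {
  set.seed(2)
  one <- matrix(rnorm(512 * 2), 512, 2)
  sig <- make_signal(rbind(one, one, one), fs = 256)
  ep <- segment_epochs(sig, overlap_s = 0)   # three identical epochs
  avg <- average_spectrum(ep)
  expect_equal(avg$power, t(epoch_spectrum(one)$power),
               ignore_attr = TRUE)

  long <- make_signal(matrix(rnorm(256 * 401 * 2), ncol = 2), fs = 256)
  eps <- segment_epochs(long)
  expect_equal(average_spectrum(eps, truncate_to = 334)$n_epochs, 334)
  expect_error(average_spectrum(eps, truncate_to = 1000), "exceeds")
})

test_that("bin-wise standard error shrinks like 1/sqrt(epoch count)", {
  sd_at <- function(n_ep, reps = 25) {
    vals <- vapply(seq_len(reps), function(r) {
      set.seed(1000 * n_ep + r)
      sig <- make_signal(matrix(rnorm(256 * (n_ep + 1)), ncol = 1), 256)
      average_spectrum(segment_epochs(sig))$power[1, 20]
    }, 0)
    stats::sd(vals)
  }
  ratio <- sd_at(50) / sd_at(200)
  expect_gt(ratio, 1.4)      # ideal ratio 2 under independence
  expect_lt(ratio, 2.8)
})

test_that("amplitude criterion rejects exactly the contaminated second", {
  set.seed(3)
  x <- matrix(rnorm(10 * 256 * 3, sd = 10), ncol = 3)
  x[256 * 4 + 100, 2] <- 500          # spike inside second 5
  rej <- reject_artifact_epochs(make_signal(x, 256), amp_uv = 100)
  expect_identical(which(!rej$quality$keep), 5L)
  expect_equal(nrow(rej$signal$data), 9 * 256)

  clean <- reject_artifact_epochs(
    make_signal(matrix(rnorm(9 * 256 * 3, sd = 10), ncol = 3), 256),
    amp_uv = 100)
  expect_true(all(clean$quality$keep))
})

test_that("spatially deviant epochs are caught by the sSTD criterion", {
  set.seed(4)
  x <- matrix(rnorm(100 * 256 * 5, sd = 10), ncol = 5)
  sec <- 37
  x[(sec - 1) * 256 + 1:256, 3] <- x[(sec - 1) * 256 + 1:256, 3] * 12
  rej <- reject_artifact_epochs(make_signal(x, 256), amp_uv = 1e9,
                                power_z = 1e9, sstd_z = 3)
  # independent z-score pass over the reported index
  q <- rej$quality
  z <- (q$sstd - mean(q$sstd)) / stats::sd(q$sstd)
  expect_equal(q$sstd_zscore, z)
  expect_gt(z[sec], 3)
  expect_false(q$keep[sec])

  expect_error(reject_artifact_epochs(make_signal(matrix(1e4, 512, 2), 256),
                                      amp_uv = 100), "all epochs")
})

test_that("the spectra pipeline is deterministic end to end", {
  tr <- sample_subject(make_group_profile("AD", 1), seed = 6)
  sig <- synthesize_timeseries(tr, duration_s = 40, fs = 256,
                               artifact_rate = 0.05, seed = 10)
  a <- subject_spectra(sig, id = "a")
  b <- subject_spectra(sig, id = "a")
  expect_identical(a$power, b$power)
  expect_true(all(a$power >= 0))
})
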