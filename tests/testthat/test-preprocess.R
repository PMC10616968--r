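test_that("resampling decimates with negligible in-band amplitude loss", {
  srate <- 512
  tt <- (0:(2.5 * srate - 1)) / srate
  raw <- eeg_recording(matrix(sin(2 * pi * 10 * tt), 1), srate)
  out <- resample_recording(raw, 256)
  expect_equal(ncol(out$data), 640)            # 2.5 s at 256 Hz
  expect_equal(out$srate, 256)
  # FFT amplitude of the surviving 10 Hz component within 1%
  amp <- 2 * Mod(fft(out$data[1, ]))[round(10 * 640 / 256) + 1] / 640
  expect_gt(amp, 0.99)
  expect_error(resample_recording(out, 512), "upsampling")
  # even-length input halves exactly
  raw2 <- eeg_recording(matrix(rnorm(1024), 1), 512)
  expect_equal(ncol(resample_recording(raw2, 256)$data), 512)
})

test_that("high-pass removes DC and drift but passes 10 Hz", {
  co <- butter_coeffs(4, 1 / 128, "high")
  fr <- eegpipe:::freq_response(co$b, co$a, c(0.1, 10), 256)
  expect_lt(40 * log10(fr[1]), -20)            # forward-backward doubles dB
  expect_gt(40 * log10(fr[2]), -1)
  raw <- eeg_recording(matrix(5, 2, 2000), 256)
  out <- highpass_filter(raw, 1)
  expect_lt(max(abs(out$data)), 1e-6)
  set.seed(1)
  raw2 <- eeg_recording(matrix(rnorm(4000, mean = 3), 1, 4000), 256)
  # the 3 uV offset is removed; residual mean is filtered-noise fluctuation
  expect_lt(abs(mean(highpass_filter(raw2, 1)$data)), 0.05)
})

test_that("notch attenuates line frequency without touching neighbours", {
  srate <- 256
  tt <- (0:(8 * srate - 1)) / srate
  x <- sin(2 * pi * 60 * tt) + sin(2 * pi * 10 * tt)
  raw <- eeg_recording(matrix(x, 1), srate)
  out <- notch_line_noise(raw, 60)
  p60_in <- fft_band_power(x, srate, 59.5, 60.5)
  p60_out <- fft_band_power(out$data[1, ], srate, 59.5, 60.5)
  expect_lt(10 * log10(p60_out / p60_in), -20)
  p10_in <- fft_band_power(x, srate, 9.5, 10.5)
  p10_out <- fft_band_power(out$data[1, ], srate, 9.5, 10.5)
  expect_lt(abs(10 * log10(p10_out / p10_in)), 1)
  # frequency response outside the +/-2 Hz exclusion altered < 1 dB
  co <- notch_coeffs(60, srate)
  f <- setdiff(seq(2, 120, 0.5), seq(58, 62, 0.5))
  f <- f[f < srate / 2 | f < 118]
  fr <- eegpipe:::freq_response(co$b, co$a, f[f <= 126], srate)
  expect_lt(max(abs(40 * log10(fr[abs(f - 60) > 2 & abs(f - 120) > 2]))), 1)
  expect_identical(notch_line_noise(raw, NULL), raw)
})

test_that("common median reference zeroes the channel median pointwise", {
  raw <- eeg_recording(rbind(c(1, 4), c(2, 6), c(5, 9)), 100)
  out <- common_median_reference(raw)
  expect_equal(out$data[, 1], c(-1, 0, 3))
  # identical channels -> zeros; idempotence; EMG/sync untouched
  set.seed(2)
  X <- rbind(matrix(rnorm(5 * 50), 5), matrix(rnorm(50), 1))
  raw2 <- eeg_recording(X, 100, kinds = c(rep("EEG", 5), "EMG"))
  out2 <- common_median_reference(raw2)
  expect_close(apply(out2$data[1:5, ], 2, median), 0, 1e-12)
  expect_identical(out2$data[6, ], X[6, ])
  expect_equal(common_median_reference(out2)$data, out2$data, tolerance = 1e-12)
})

test_that("average reference zeroes the group mean and nothing else", {
  X <- rbind(a = c(2, 4), b = c(0, 2), e = c(9, 9))
  raw <- eeg_recording(X, 10, kinds = c("EEG", "EEG", "EMG"))
  out <- average_reference(raw, "EEG")
  expect_equal(unname(out$data[1:2, ]), rbind(c(1, 1), c(-1, -1)))
  expect_identical(out$data[3, ], X[3, ])
  expect_close(colMeans(average_reference(out, "EMG")$data[3, , drop = FALSE]), 0, 1e-12)
})

test_that("channel statistics match their distributional contracts", {
  set.seed(5)
  n <- 1e5
  shared <- rnorm(n)
  X <- rbind(shared + 0.1 * rnorm(n),
             shared + 0.1 * rnorm(n),
             shared + 0.1 * rnorm(n),
             shared + 0.1 * rnorm(n),
             rnorm(n))                      # independent channel
  raw <- eeg_recording(X, 100)
  st <- compute_channel_stats(raw, window = 1)
  expect_close(st$kurtosis[1:4], 3, 0.2)     # Gaussian Pearson kurtosis
  expect_lt(max(st$uncorrelated_fraction[1:4]), 0.01)
  expect_gt(st$uncorrelated_fraction[5], 0.9)
  expect_error(compute_channel_stats(eeg_recording(X[, 1:500], 100)),
               "10 analysis windows")
})

test_that("population criteria flag exactly the constructed outliers", {
  set.seed(11)
  shared <- rnorm(20000)
  X <- matrix(0.8 * rep(shared, each = 32) + 0.4 * rnorm(32 * 20000), 32)
  X[7, ] <- 10 * rnorm(20000)               # high SD, and decorrelated
  raw <- eeg_recording(X, 200)
  st <- compute_channel_stats(raw)
  rep <- flag_bad_channels(st)
  expect_equal(rep$bad_channels, 7L)
  expect_true("high_sd" %in% rep$criteria[[1]])
  expect_equal(rep$retained, 31)

  # homogeneous channels: no flags at this fixed seed
  set.seed(12)
  raw2 <- eeg_recording(
    matrix(0.8 * rep(shared[1:20000], each = 16) + 0.4 * rnorm(16 * 20000), 16),
    200)
  rep2 <- flag_bad_channels(compute_channel_stats(raw2))
  expect_length(rep2$bad_channels, 0)

  # manual list always honoured
  rep3 <- flag_bad_channels(compute_channel_stats(raw2), manual = 3)
  expect_true(3 %in% rep3$bad_channels)
  expect_true("manual" %in% rep3$criteria[[1]])
})

test_that("spherical-spline interpolation rebuilds predictable channels", {
  rec <- simulate_recording(sim_config(duration = 20, seed = 6),
                            bad_channel_modes = NULL, n_muscle_bursts = 0)
  raw <- rec$raw
  eeg <- channel_indices(raw, "EEG")
  # make channel 5 exactly the mean of its spatial neighbours, then rebuild it
  nb <- eegpipe:::neighbour_sets(raw, 4)[[5]]
  raw$data[eeg[5], ] <- colMeans(raw$data[eeg[nb], ])
  out <- interpolate_channels(raw, eeg[5])
  expect_gt(cor(out$data[eeg[5], ], raw$data[eeg[5], ]), 0.95)
  # good channels untouched; no-bad-channel call is the identity
  expect_identical(out$data[eeg[1], ], raw$data[eeg[1], ])
  expect_identical(interpolate_channels(raw, integer(0)), raw)
  # interpolated channel variance bounded by its neighbourhood
  expect_lt(var(out$data[eeg[5], ]),
            1.5 * max(apply(raw$data[eeg[nb], ], 1, var)))
  expect_error(interpolate_channels(raw, eeg[1:20]), "more than half")
})
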