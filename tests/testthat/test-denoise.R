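make_baseline <- function(seed = 11, duration = 120) {
  simulate_recording(sim_config(duration = duration, seed = seed),
                     bad_channel_modes = NULL, n_muscle_bursts = 0)$raw
}

test_that("ASR calibration is deterministic and diagonalizes the baseline", {
  base <- make_baseline()
  m1 <- asr_calibrate(base, 20, 0.5)
  m2 <- asr_calibrate(base, 20, 0.5)
  expect_identical(m1, m2)
  expect_true(all(m1$thresholds > 0))
  # axes orthonormal and diagonalizing: off-diagonal covariance ~ 0
  eeg <- channel_indices(base, "EEG")
  Xc <- base$data[eeg, ] - rowMeans(base$data[eeg, ])
  C <- crossprod(m1$axes, Xc %*% t(Xc) %*% m1$axes) / ncol(Xc)
  expect_lt(max(abs(C[upper.tri(C)])) / max(diag(C)), 1e-8)
  expect_close(crossprod(m1$axes), diag(nrow(C)), 1e-8)
  short <- base; short$data <- short$data[, 1:1000]
  expect_error(asr_calibrate(short), "10 calibration windows")
})

test_that("ASR passes matched data, removes bursts, preserves zero", {
  base <- make_baseline(11)
  model <- asr_calibrate(base, 20, 0.5)
  same <- make_baseline(12)            # statistically matching, different seed
  res <- asr_clean(same, model)
  eeg <- channel_indices(same, "EEG")
  expect_gt(cor(as.vector(res$raw$data[eeg, ]), as.vector(same$data[eeg, ])), 0.99)

  # 10x burst along the leading principal axis is pulled below threshold
  X <- same$data[eeg, ]
  idx <- 5000:5400
  X[, idx] <- X[, idx] + model$axes[, 1] %*%
    t(rnorm(length(idx), sd = 10 * sqrt(mean(model$thresholds^2))))
  burst <- same; burst$data[eeg, ] <- X
  res2 <- asr_clean(burst, model)
  S <- crossprod(model$axes, res2$raw$data[eeg, idx])
  expect_lt(sqrt(mean(S[1, ]^2)), model$thresholds[1])
  expect_gt(res2$log$n_flagged, 0)

  zero <- same; zero$data[] <- 0
  expect_equal(max(abs(asr_clean(zero, model)$raw$data)), 0)

  mism <- drop_channels(same, eeg[1])
  expect_error(asr_clean(mism, model), "does not match")
})

test_that("ASR only alters the flagged subspace", {
  base <- make_baseline(11)
  model <- asr_calibrate(base, 20, 0.5)
  same <- make_baseline(12)
  eeg <- channel_indices(same, "EEG")
  X <- same$data[eeg, ]
  idx <- 3000:3200
  X[, idx] <- X[, idx] + model$axes[, 2] %*% t(rnorm(length(idx), sd = 50 * model$thresholds[2]))
  burst <- same; burst$data[eeg, ] <- X
  out <- asr_clean(burst, model)$raw$data[eeg, ]
  keepax <- setdiff(seq_len(nrow(X)), 2)
  pin <- crossprod(model$axes[, keepax], X[, idx])
  pout <- crossprod(model$axes[, keepax], out[, idx])
  expect_gt(cor(as.vector(pin), as.vector(pout)), 0.99)
})

test_that("EEMD reconstructs, separates tones, and degenerates to EMD", {
  set.seed(3)
  t <- (0:2047) / 512
  x <- sin(2 * pi * 40 * t) + 2 * sin(2 * pi * 5 * t)
  dec <- eemd(x, n_ensembles = 50, noise_sd_fraction = 0.1, max_imfs = 6)
  recon <- colSums(dec$imfs) + dec$residue
  expect_lt(sqrt(sum((recon - x)^2) / sum(x^2)), 0.01)
  expect_gt(cor(dec$imfs[1, ], sin(2 * pi * 40 * t)), 0.9)
  # IMF ordering high -> low frequency
  cent <- apply(dec$imfs, 1, function(im) {
    sp <- Mod(fft(im))^2
    f <- (seq_along(sp) - 1) * 512 / length(sp)
    half <- f <= 256
    sum(sp[half] * f[half]) / sum(sp[half])
  })
  expect_true(all(diff(cent[1:3]) < 0))

  # pink-noise reconstruction identity
  set.seed(4)
  p <- cumsum(rnorm(1500)); p <- p - mean(p)
  dp <- eemd(p, n_ensembles = 20, noise_sd_fraction = 0.1, max_imfs = 8)
  expect_lt(sqrt(sum((colSums(dp$imfs) + dp$residue - p)^2) / sum(p^2)), 0.01)

  # n_ensembles = 1 / noise 0 equals a plain EMD reference run
  d1 <- eemd(x, n_ensembles = 1, noise_sd_fraction = 0, max_imfs = 6)
  ref <- eegpipe:::emd_cpp(x, 6L, 12L, 0.2)
  expect_equal(d1$imfs, ref$imfs)

  # linear-trend invariance of IMF1
  d2 <- eemd(x + 5, n_ensembles = 1, noise_sd_fraction = 0, max_imfs = 6)
  expect_close(d1$imfs[1, ], d2$imfs[1, ], 1e-6)

  expect_error(eemd(c(x[1:100], NA)), "non-finite")
})

test_that("CCA orders by autocorrelation and removes dominant variance", {
  set.seed(6)
  n <- 3000
  co <- butter_coeffs(2, 0.2, "low")
  S <- rbind(50 * filtfilt_iir(co$b, co$a, rnorm(n)),
             matrix(rnorm(7 * n), 7))
  A <- qr.Q(qr(matrix(rnorm(64), 8)))   # orthogonal: equal background variances
  X <- A %*% S
  res <- cca_suppress_imf1(X)
  expect_true(all(res$cca$correlations >= 0 & res$cca$correlations <= 1))
  expect_true(all(diff(res$cca$correlations) <= 1e-8))
  expect_equal(length(res$removed), 1)
  expect_equal(which.max(res$cca$variances), res$removed)
  tot_in <- sum(apply(X, 1, var))
  expect_lte(sum(apply(res$cleaned, 1, var)), tot_in * (1 + 1e-9))

  # channel scaling leaves canonical correlations unchanged
  res2 <- cca_suppress_imf1(diag(c(10, rep(1, 7))) %*% X)
  expect_close(res$cca$correlations, res2$cca$correlations, 1e-6)

  # duplicate dataset at delay 0: first canonical correlation is 1
  res0 <- cca_suppress_imf1(X, delay = 0)
  expect_equal(res0$cca$correlations[1], 1, tolerance = 1e-8)

  # rank-deficient input is PCA-reduced, flagged, and still returns
  Xr <- rbind(X, X[1, ])
  resr <- cca_suppress_imf1(Xr)
  expect_true(resr$cca$rank_reduced)
})

test_that("full denoise removes muscle-burst power and spares brain alpha", {
  # denoising operates at the pipeline rate (256 Hz), where the 30-100 Hz
  # muscle band occupies the first intrinsic mode
  rec <- simulate_recording(sim_config(duration = 60, seed = 15),
                            bad_channel_modes = NULL, n_muscle_bursts = 4)
  raw <- resample_recording(rec$raw, 256)
  base <- resample_recording(make_baseline(16, 60), 256)
  model <- asr_calibrate(base, 20, 0.5)
  out <- apply_denoise(raw, asr = model, n_ensembles = 10)
  eeg <- channel_indices(raw, "EEG")
  hi_in <- hi_out <- alpha_in <- alpha_out <- 0
  for (sg in rec$ground_truth$artifact_segments) {
    i <- round(sg$start * 256):round(sg$end * 256)
    for (ch in sg$channels) {
      hi_in <- hi_in + fft_band_power(raw$data[ch, i], 256, 30, 100)
      hi_out <- hi_out + fft_band_power(out$raw$data[ch, i], 256, 30, 100)
    }
  }
  clean_i <- round(2 * 256):round(8 * 256)
  for (ch in eeg[1:6]) {
    alpha_in <- alpha_in + fft_band_power(raw$data[ch, clean_i], 256, 8, 13)
    alpha_out <- alpha_out + fft_band_power(out$raw$data[ch, clean_i], 256, 8, 13)
  }
  expect_lt(hi_out / hi_in, 0.5)               # >= 50% burst power removed
  expect_lt(abs(alpha_out / alpha_in - 1), 0.1)  # alpha within 10%
  expect_equal(out$log$stages, c("asr", "eemd", "cca"))

  # artifact-free input passes nearly unchanged
  clean <- resample_recording(make_baseline(17, 60), 256)
  out2 <- apply_denoise(clean, asr = model, n_ensembles = 10)
  expect_gt(cor(as.vector(out2$raw$data[eeg, ]), as.vector(clean$data[eeg, ])), 0.95)
})
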