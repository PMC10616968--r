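test_that("Morlet transform is amplitude-calibrated and edge-trimmed", {
  srate <- 256
  tt <- seq(-1, 3 - 1 / srate, 1 / srate)
  M <- matrix(rep(sin(2 * pi * 10 * tt), 3), 3, byrow = TRUE)
  ep <- make_epochs(M, srate, -1)
  tf <- morlet_tfr(ep)
  fi <- which.min(abs(tf$freqs - 10))
  pw <- Mod(tf$coef[1, fi, ])^2
  expect_lt(sd(pw) / mean(pw), 0.05)           # flat across retained times
  expect_equal(mean(sqrt(pw)), 1, tolerance = 0.01)   # unit amplitude
  expect_equal(tf$freqs[which.max(rowMeans(Mod(tf$coef[1, , ])^2))],
               tf$freqs[fi])
  # trimmed by half the longest wavelet on each side
  expect_gt(min(tf$times), -1)
  expect_lt(max(tf$times), 3)

  zero <- make_epochs(matrix(0, 2, length(tt)), srate, -1)
  expect_equal(max(Mod(morlet_tfr(zero)$coef)), 0)

  short <- make_epochs(matrix(rnorm(2 * 128), 2), srate, 0)
  expect_error(morlet_tfr(short), "feasible")
})

test_that("median ERSP has the stated dB semantics and outlier robustness", {
  srate <- 256
  tt <- seq(-1, 3 - 1 / srate, 1 / srate)
  set.seed(8)
  n_tr <- 60
  base <- matrix(rnorm(n_tr * length(tt)), n_tr)
  ep <- make_epochs(base, srate, -1)
  tf <- morlet_tfr(ep)
  er <- compute_ersp(tf, c(-0.5, 0))
  expect_lt(abs(mean(er$values)), 0.3)         # stationary: ~0 dB

  # doubling post-event power in every trial at all frequencies: +3.01 dB
  gain <- ifelse(tt >= 0.5, sqrt(2), 1)
  ep2 <- make_epochs(base * matrix(gain, n_tr, length(tt), byrow = TRUE), srate, -1)
  er2 <- compute_ersp(morlet_tfr(ep2), c(-0.5, 0))
  late <- er2$times > 0.8 & er2$times < 2.5
  expect_equal(mean(er2$values[, late]), 10 * log10(2), tolerance = 0.35)

  # single 100x-power trial: median shifts < 0.2 dB, mean shifts > 1 dB
  out <- base; out[1, ] <- out[1, ] * 10
  ero <- compute_ersp(morlet_tfr(make_epochs(out, srate, -1)), c(-0.5, 0))
  erm <- compute_ersp(morlet_tfr(make_epochs(out, srate, -1)), c(-0.5, 0),
                      average = "mean")
  ref_m <- compute_ersp(tf, c(-0.5, 0), average = "mean")
  expect_lt(mean(abs(ero$values - er$values)), 0.2)
  expect_gt(max(abs(erm$values - ref_m$values)), 1)

  # global gain invariance (ratio statistic)
  erg <- compute_ersp(morlet_tfr(make_epochs(base * 7, srate, -1)), c(-0.5, 0))
  expect_close(erg$values, er$values, 1e-9)
})

test_that("bootstrap ERSP mask is calibrated and degenerate at alpha = 1", {
  srate <- 256
  tt <- seq(-1.5, 3 - 1 / srate, 1 / srate)
  set.seed(3)
  ep <- make_epochs(matrix(rnorm(60 * length(tt)), 60), srate, -1.5)
  tf <- morlet_tfr(ep)
  em <- ersp_bootstrap_mask(tf, baseline = c(-1, 0), alpha = 0.05, n_boot = 400)
  expect_lt(mean(em$mask), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  expect_true(all(em$values[!em$mask] == 0))

  em1 <- ersp_bootstrap_mask(tf, baseline = c(-1, 0), alpha = 1, n_boot = 400)
  expect_true(all(em1$mask))
  expect_error(ersp_bootstrap_mask(tf, n_boot = 50), "n_boot")

  # injected +6 dB cell is detected with high power
  x <- ep$data[, 1, ]
  gain <- ifelse(tt >= 0.5 & tt < 1.5, 10^(6 / 20), 1)
  ep2 <- make_epochs(x * matrix(gain, 60, length(tt), byrow = TRUE), srate, -1.5)
  em2 <- ersp_bootstrap_mask(morlet_tfr(ep2), baseline = c(-1, 0),
                             alpha = 0.05, n_boot = 400)
  eff <- em2$times > 0.7 & em2$times < 1.3
  expect_gt(mean(em2$mask[, eff]), 0.9)
})

test_that("ITC matches its exact and asymptotic values", {
  srate <- 256
  tt <- seq(-1, 2 - 1 / srate, 1 / srate)
  # identical trials -> ITC 1 everywhere (with nonzero coefficients)
  M <- matrix(rep(sin(2 * pi * 10 * tt), 4), 4, byrow = TRUE)
  it1 <- compute_itc(morlet_tfr(make_epochs(M, srate, -1)))
  fi <- which.min(abs(it1$freqs - 10))
  expect_close(it1$values[fi, ], 1, 1e-6)

  # two opposite-phase trials -> ITC 0 at the carrier frequency
  M2 <- rbind(sin(2 * pi * 10 * tt), -sin(2 * pi * 10 * tt))
  it2 <- compute_itc(morlet_tfr(make_epochs(M2, srate, -1)))
  expect_lt(max(it2$values[fi, ]), 1e-6)

  # amplitude scaling per trial leaves ITC unchanged (phase-only statistic)
  set.seed(5)
  M3 <- matrix(rnorm(20 * length(tt)), 20)
  tf3 <- morlet_tfr(make_epochs(M3, srate, -1))
  tf3s <- tf3; tf3s$coef <- tf3$coef * array(runif(20, 0.1, 10), dim(tf3$coef))
  expect_close(compute_itc(tf3)$values, compute_itc(tf3s)$values, 1e-9)

  one <- make_epochs(M3[1, , drop = FALSE], srate, -1)
  expect_error(compute_itc(morlet_tfr(one)), "single trial")

  # E[ITC] for n uniform phases ~ sqrt(pi)/(2 sqrt(n))
  set.seed(6)
  sims <- replicate(1000, Mod(mean(exp(1i * runif(100, -pi, pi)))))
  expect_lt(abs(mean(sims) - sqrt(pi) / (2 * sqrt(100))), 0.01)
})

test_that("ITC mask calibrates on null data and normalizes by baseline", {
  srate <- 256
  tt <- seq(-1.5, 3 - 1 / srate, 1 / srate)
  set.seed(4)
  ep <- make_epochs(matrix(rnorm(60 * length(tt)), 60), srate, -1.5)
  tf <- morlet_tfr(ep)
  im <- itc_significance_mask(tf, baseline = c(-1, 0), alpha = 0.05, n_boot = 400)
  expect_lt(mean(im$mask), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  expect_true(all(im$values[!im$mask] == 0))
  # subtracting the per-frequency baseline mean from a constant-ITC map -> 0
  bidx <- im$times >= -1 & im$times < 0
  resid <- im$raw_values - rowMeans(im$raw_values[, bidx])
  expect_close(im$values[im$mask], resid[im$mask], 1e-9)
})

test_that("band summaries reduce maps as documented", {
  map <- list(values = matrix(1:12, 3, 4), freqs = c(5, 10, 20),
              times = 1:4)
  class(map) <- "ersp_map"
  out <- band_summary(map, list(theta = c(4, 8)))
  expect_equal(unname(out[1, ]), as.numeric(map$values[1, ]))  # single row
  flat <- map; flat$values <- matrix(2, 3, 4)
  expect_close(band_summary(flat, list(alpha = c(8, 13)))[1, ], 2, 1e-12)
  expect_error(band_summary(map, list(gamma = c(50, 80))), "empty band")
  # +3 dB across 8-13 Hz shows up as +3 dB in the alpha course
  m2 <- map; m2$values <- matrix(0, 3, 4); m2$values[2, 3:4] <- 3
  bs <- band_summary(m2, list(alpha = c(8, 13)))
  expect_equal(unname(bs[1, ]), c(0, 0, 3, 3))
})

test_that("increasing reset concentration never decreases peak ITC", {
  cfg <- sim_config(duration = 290, seed = 5)
  set.seed(cfg$seed)
  sch <- generate_event_schedule(cfg)
  pad <- tfr_pad()
  peaks <- vapply(c(0, 5, 50), function(kap) {
    set.seed(100 + kap)
    eff <- list(event_effect("src_alpha", "occlusion_onset", "phase_reset",
                             magnitude = kap, duration = 400))
    sim <- synthesize_sources(cfg, default_sources(), eff, sch)
    ep <- epoch_recording(matrix(sim$signals["src_alpha", ], 1), sch,
                          tmin = -0.5 - pad, tmax = 2 + pad, srate = cfg$srate)
    tf <- morlet_tfr(ep)
    it <- compute_itc(tf)
    arows <- it$freqs >= 8 & it$freqs <= 13
    max(it$values[arows, it$times >= 0 & it$times <= 0.8])
  }, 0)
  expect_true(all(diff(peaks) > -0.05))
  expect_gt(peaks[3], peaks[1])
})
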