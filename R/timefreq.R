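#' Default log-spaced analysis frequency grid (4-100 Hz, 50 bins)
#' @param fmin,fmax grid limits, Hz.
#' @param n number of bins.
#' @return numeric vector of frequencies.
#' @export
default_freq_grid <- function(fmin = 4, fmax = 100, n = 50)
  exp(seq(log(fmin), log(fmax), length.out = n))

#' Morlet wavelet time-frequency decomposition
#'
#' Complex convolution of one channel's epochs with L2-area-normalized Morlet
#' wavelets; the number of cycles grows as
#' `cycles_base * (f / min(f))^cycle_exponent`. The gain is set so that a
#' unit-amplitude sinusoid at a grid frequency yields |coefficient| of about 1.
#' Times within half the longest wavelet of either epoch edge are trimmed.
#'
#' @param epochs an `eeg_epochs`.
#' @param freqs frequency grid, Hz (default [default_freq_grid()]).
#' @param cycles_base cycles at the lowest frequency.
#' @param cycle_exponent exponent of the cycle schedule.
#' @param channel channel index within the epochs.
#' @param support wavelet support half-width in Gaussian SDs.
#' @return a `tf_decomposition`: complex `coef` (trials x freqs x times),
#'   `freqs`, `times`, `srate`, `cycles`.
#' @export
morlet_tfr <- function(epochs, freqs = default_freq_grid(), cycles_base = 3,
                       cycle_exponent = 0.5, channel = 1, support = 3.5) {
  stopifnot(inherits(epochs, "eeg_epochs"), all(diff(freqs) > 0))
  srate <- epochs$srate
  X <- epochs$data[, channel, , drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  n <- ncol(X); n_tr <- nrow(X)
  cycles <- cycles_base * (freqs / min(freqs))^cycle_exponent
  sig_t <- cycles / (2 * pi * freqs)
  half <- ceiling(support * sig_t * srate)
  if (2 * max(half) >= n)
    stop(sprintf(paste0("lowest frequency infeasible for this window; ",
                        "minimum feasible is about %.2f Hz"),
                 support * cycles_base * srate / (2 * pi * (n / 2 - 1))))
  trim <- max(half)
  keep <- (trim + 1):(n - trim)
  nfft <- 2^ceiling(log2(n + 2 * max(half)))
  Xp <- rbind(t(X), matrix(0, nfft - n, n_tr))     # nfft x trials
  FX <- stats::mvfft(Xp)
  coef <- array(0i, dim = c(n_tr, length(freqs), length(keep)))
  for (fi in seq_along(freqs)) {
    h <- half[fi]
    tt <- (-h:h) / srate
    env <- exp(-tt^2 / (2 * sig_t[fi]^2))
    w <- env * exp(2i * pi * freqs[fi] * tt) * (2 / sum(env))
    FW <- stats::fft(c(w, rep(0 + 0i, nfft - length(w))))
    conv <- stats::mvfft(FX * FW, inverse = TRUE) / nfft
    coef[, fi, ] <- t(conv[keep + h, , drop = FALSE])  # wavelet centre at lag h
  }
  structure(list(coef = coef, freqs = freqs, times = epochs$times[keep],
                 srate = srate, cycles = cycles),
            class = "tf_decomposition")
}

baseline_indices <- function(tf, baseline) {
  idx <- which(tf$times >= baseline[1] & tf$times < baseline[2])
  if (length(idx) == 0)
    stop("empty baseline after edge trimming: available times [",
         round(min(tf$times), 3), ", ", round(max(tf$times), 3), "]")
  idx
}

#' Median-based event-related spectral perturbation
#'
#' Per trial, power is |coefficient|^2; the median across trials is taken per
#' time-frequency cell and expressed in dB relative to the mean over baseline
#' times of the median power at that frequency:
#' 10*log10(medP(f,t) / baseP(f)).
#'
#' @param tf a `tf_decomposition`.
#' @param baseline c(start, end) seconds relative to the event.
#' @param average "median" (default) or "mean" across trials.
#' @return an `ersp_map`: `values` (dB, freqs x times), `freqs`, `times`,
#'   `baseline`; `mask` is NULL until a bootstrap mask is applied.
#' @export
compute_ersp <- function(tf, baseline = c(-0.5, 0), average = "median") {
  P <- Mod(tf$coef)^2
  medP <- if (average == "median") median_over_trials(P) else
    colMeans(array(P, dim = c(dim(P)[1], prod(dim(P)[2:3]))))
  if (is.null(dim(medP))) medP <- matrix(medP, dim(P)[2], dim(P)[3])
  bidx <- baseline_indices(tf, baseline)
  baseP <- rowMeans(medP[, bidx, drop = FALSE])
  vals <- 10 * log10(sweep(medP, 1, baseP, "/"))
  structure(list(values = vals, freqs = tf$freqs, times = tf$times,
                 baseline = baseline, mask = NULL, alpha = NULL),
            class = "ersp_map")
}

# median across trials of a trials x freqs x times power array
median_over_trials <- function(P) {
  d <- dim(P)
  matrix(col_median_cpp(array(P, dim = c(d[1], d[2] * d[3]))), d[2], d[3])
}

# index helper: value[row_draw[i], freq, col_draw[i]] for all freqs
boot_draw <- function(A, cols, rows = seq_len(dim(A)[1])) {
  n_tr <- length(rows); nf <- dim(A)[2]
  idx <- cbind(rep(rows, times = nf),
               rep(seq_len(nf), each = n_tr),
               rep(cols, times = nf))
  matrix(A[idx], n_tr, nf)
}

#' Bootstrap significance mask for an ERSP map
#'
#' The surrogate distribution is built by resampling baseline time points
#' (with replacement, independently per trial) together with a trial
#' bootstrap, recomputing the median-based dB statistic `n_boot` times per
#' frequency. The surrogate's baseline normalizer is resampled independently
#' by a circular block bootstrap of baseline time points (block length twice
#' the wavelet SD at that frequency), so the null reflects the uncertainty of
#' the normalizer as well; without this the null is conditionally too narrow
#' at low frequencies and the pointwise test over-rejects. Cells inside the
#' two-tailed (alpha/2, 1-alpha/2) surrogate quantiles are set to 0 dB.
#'
#' @param tf a `tf_decomposition`.
#' @param baseline baseline window, s.
#' @param alpha two-tailed level (alpha = 1 masks nothing).
#' @param n_boot number of bootstrap iterations (>= 200).
#' @return an `ersp_map` with `values` masked (non-significant cells 0 dB),
#'   `raw_values`, and the logical `mask`.
#' @export
ersp_bootstrap_mask <- function(tf, baseline = c(-0.5, 0), alpha = 0.05,
                                n_boot = 500) {
  stopifnot(n_boot >= 200)
  ersp <- compute_ersp(tf, baseline)
  if (alpha >= 1) {
    ersp$mask <- matrix(TRUE, nrow(ersp$values), ncol(ersp$values))
    ersp$raw_values <- ersp$values
    ersp$alpha <- alpha
    return(ersp)
  }
  P <- Mod(tf$coef)^2
  bidx <- baseline_indices(tf, baseline)
  Pb <- P[, , bidx, drop = FALSE]
  n_tr <- dim(P)[1]; nf <- dim(P)[2]; nb <- length(bidx)
  medP <- median_over_trials(P)
  baseP <- rowMeans(medP[, bidx, drop = FALSE])
  # block length per frequency: ~2 wavelet SDs, the within-trial power
  # correlation scale
  blk <- pmin(pmax(ceiling(2 * tf$cycles / (2 * pi * tf$freqs) * tf$srate), 1), nb)
  null <- matrix(0, n_boot, nf)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n_tr, n_tr, replace = TRUE)
    cols <- sample.int(nb, n_tr, replace = TRUE)
    m <- col_median_cpp(boot_draw(Pb, cols, rows))
    basePb <- vapply(seq_len(nf), function(f) {
      st <- sample.int(nb, ceiling(nb / blk[f]), replace = TRUE)
      sel <- (as.vector(outer(0:(blk[f] - 1), st, "+")) %% nb) + 1
      mean(medP[f, bidx[sel[seq_len(nb)]]])
    }, 0)
    null[b, ] <- 10 * log10(m / basePb)
  }
  qlo <- apply(null, 2, stats::quantile, probs = alpha / 2, names = FALSE)
  qhi <- apply(null, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  mask <- sweep(ersp$values, 1, qlo, "<") | sweep(ersp$values, 1, qhi, ">")
  ersp$raw_values <- ersp$values
  ersp$values[!mask] <- 0
  ersp$mask <- mask
  ersp$alpha <- alpha
  ersp$n_boot <- n_boot
  ersp
}

#' Inter-trial coherence
#'
#' ITC(f,t) is the magnitude of the across-trial mean of unit-length phase
#' vectors. Trials with zero coefficient magnitude at a cell are excluded from
#' that cell's mean.
#'
#' @param tf a `tf_decomposition` with at least 2 trials.
#' @return an `itc_map` with raw `values` in \[0,1\].
#' @export
compute_itc <- function(tf) {
  if (dim(tf$coef)[1] < 2)
    stop("ITC undefined for a single trial")
  mag <- Mod(tf$coef)
  u <- tf$coef / ifelse(mag > 0, mag, 1)
  u[mag == 0] <- 0i
  dd <- dim(u)
  counts <- matrix(colSums(array(mag > 0, dim = c(dd[1], dd[2] * dd[3]))), dd[2], dd[3])
  vals <- matrix(Mod(colSums(array(u, dim = c(dd[1], dd[2] * dd[3])))), dd[2], dd[3]) /
    pmax(counts, 1)
  structure(list(values = vals, freqs = tf$freqs, times = tf$times,
                 mask = NULL, baseline = NULL),
            class = "itc_map")
}

#' Significance-masked, baseline-normalized inter-trial coherence
#'
#' A surrogate ITC distribution is built per frequency by resampling baseline
#' time points per trial. The per-frequency mean baseline ITC is subtracted
#' from the map ("normalization"); cells whose raw ITC lies inside the
#' two-tailed surrogate bounds are set to 0.
#'
#' @inheritParams ersp_bootstrap_mask
#' @return an `itc_map` with `values` (baseline-subtracted, masked),
#'   `raw_values` and `mask`.
#' @export
itc_significance_mask <- function(tf, baseline = c(-0.5, 0), alpha = 0.05,
                                  n_boot = 500) {
  stopifnot(n_boot >= 200)
  itc <- compute_itc(tf)
  bidx <- baseline_indices(tf, baseline)
  mag <- Mod(tf$coef)
  u <- tf$coef / ifelse(mag > 0, mag, 1)
  u[mag == 0] <- 0i
  ub <- u[, , bidx, drop = FALSE]
  n_tr <- dim(u)[1]; nf <- dim(u)[2]; nb <- length(bidx)
  null <- matrix(0, n_boot, nf)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n_tr, n_tr, replace = TRUE)
    cols <- sample.int(nb, n_tr, replace = TRUE)
    null[b, ] <- Mod(colSums(boot_draw(ub, cols, rows))) / n_tr
  }
  qlo <- apply(null, 2, stats::quantile, probs = alpha / 2, names = FALSE)
  qhi <- apply(null, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  base_itc <- rowMeans(itc$values[, bidx, drop = FALSE])
  mask <- sweep(itc$values, 1, qlo, "<") | sweep(itc$values, 1, qhi, ">")
  norm <- sweep(itc$values, 1, base_itc)
  norm[!mask] <- 0
  itc$raw_values <- itc$values
  itc$values <- norm
  itc$mask <- mask
  itc$baseline <- baseline
  itc$alpha <- alpha
  itc$n_boot <- n_boot
  itc
}

#' Per-band time courses of a time-frequency map
#'
#' @param map an `ersp_map` or `itc_map`.
#' @param bands named list of c(f_lo, f_hi) pairs, Hz.
#' @return matrix bands x times of band-mean values.
#' @export
band_summary <- function(map, bands = list(theta = c(4, 8), alpha = c(8, 13),
                                           beta = c(13, 30))) {
  out <- matrix(0, length(bands), ncol(map$values),
                dimnames = list(names(bands), NULL))
  for (i in seq_along(bands)) {
    rows <- which(map$freqs >= bands[[i]][1] & map$freqs <= bands[[i]][2])
    if (length(rows) == 0) stop("empty band: ", names(bands)[i])
    out[i, ] <- colMeans(map$values[rows, , drop = FALSE])
  }
  out
}
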