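#' Calibrate a simplified artifact-subspace-reconstruction model
#'
#' Principal axes are the eigenvectors of the (EEG-channel) baseline
#' covariance; for each axis the threshold is the mean plus `cutoff_sd` SDs of
#' the per-window RMS of the baseline projected onto that axis. The baseline
#' should be a clean standing recording preprocessed the same way as the task
#' data (the reference protocol uses 5 minutes with a cutoff of 20 SD).
#'
#' @param baseline an `eeg_recording` (EEG channels are used).
#' @param cutoff_sd threshold in calibration-RMS standard deviations.
#' @param window window length, s.
#' @return an `asr_model` list (axes, thresholds, window, channel count).
#' @export
asr_calibrate <- function(baseline, cutoff_sd = 20, window = 0.5) {
  eeg <- channel_indices(baseline, "EEG")
  X <- baseline$data[eeg, , drop = FALSE]
  wlen <- round(window * baseline$srate)
  n_win <- floor(ncol(X) / wlen)
  if (n_win < 10) stop("baseline shorter than 10 calibration windows")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors                           # orthonormal principal axes
  S <- crossprod(V, Xc)                     # axes x time
  rms <- vapply(seq_len(n_win), function(w) {
    seg <- S[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
    sqrt(rowMeans(seg^2))
  }, numeric(nrow(S)))
  thr <- rowMeans(rms) + cutoff_sd * apply(rms, 1, stats::sd)
  structure(list(axes = V, thresholds = thr, mean_ch = mu, window = window,
                 cutoff_sd = cutoff_sd, n_channels = nrow(X)),
            class = "asr_model")
}

#' Clean burst artifacts with a calibrated ASR model
#'
#' Half-overlapping Hann-weighted windows are projected onto the calibration
#' axes; axes whose window RMS exceeds the calibrated threshold are zeroed and
#' the window is rebuilt from the retained axes, then blended by overlap-add.
#' Windows with no flagged axis pass through unchanged.
#'
#' @param raw an `eeg_recording` whose EEG channel set matches calibration.
#' @param model an `asr_model`.
#' @return list with `raw` (cleaned recording) and `log` (flagged-window
#'   bookkeeping).
#' @export
asr_clean <- function(raw, model) {
  eeg <- channel_indices(raw, "EEG")
  if (length(eeg) != model$n_channels)
    stop("channel set does not match ASR calibration")
  X <- raw$data[eeg, , drop = FALSE]
  n <- ncol(X)
  wlen <- round(model$window * raw$srate)
  hop <- floor(wlen / 2)
  V <- model$axes
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))  # Hann, no zeros
  starts <- seq(1, max(n - wlen + 1, 1), by = hop)
  Y <- matrix(0, nrow(X), n)
  wsum <- numeric(n)
  n_flagged <- 0L; n_fallback <- 0L
  for (st in starts) {
    idx <- st:min(st + wlen - 1, n)
    Xw <- X[, idx, drop = FALSE]
    S <- crossprod(V, Xw)
    rms <- sqrt(rowMeans(S^2))
    keep <- rms <= model$thresholds
    if (all(keep)) {
      Xc <- Xw
    } else if (!any(keep)) {
      n_fallback <- n_fallback + 1L
      keep[which.min(rms)] <- TRUE
      Xc <- V[, keep, drop = FALSE] %*% S[keep, , drop = FALSE]
      n_flagged <- n_flagged + 1L
    } else {
      Xc <- V[, keep, drop = FALSE] %*% S[keep, , drop = FALSE]
      n_flagged <- n_flagged + 1L
    }
    w <- win[seq_along(idx)]
    Y[, idx] <- Y[, idx] + Xc * rep(w, each = nrow(Y))
    wsum[idx] <- wsum[idx] + w
  }
  Y <- Y / rep(pmax(wsum, 1e-12), each = nrow(Y))
  raw$data[eeg, ] <- Y
  list(raw = raw, log = list(n_windows = length(starts),
                             n_flagged = n_flagged, n_fallback = n_fallback))
}

#' Ensemble empirical mode decomposition of one channel
#'
#' Complementary-pair EEMD: white noise of SD `noise_sd_fraction` times the
#' signal SD is added in +/- pairs, each member is sifted into intrinsic mode
#' functions (Huang stopping criterion), and IMFs are averaged across members.
#' The paired noise cancels exactly on averaging, so the summed IMFs plus
#' residue reconstruct the input to numerical precision.
#'
#' @param x numeric signal (>= 64 samples, finite).
#' @param n_ensembles ensemble members (rounded up to an even count).
#' @param noise_sd_fraction added-noise SD as a fraction of the signal SD.
#' @param max_imfs maximum number of IMFs to extract.
#' @return an `imf_decomposition`: `imfs` (modes x samples, high to low
#'   frequency), `residue`, and the parameters used.
#' @export
eemd <- function(x, n_ensembles = 100, noise_sd_fraction = 0.1, max_imfs = 8) {
  if (any(!is.finite(x))) stop("non-finite input")
  stopifnot(length(x) >= 64)
  res <- eemd_cpp(x, n_ensembles, noise_sd_fraction * stats::sd(x), max_imfs)
  structure(list(imfs = res$imfs, residue = as.numeric(res$residue),
                 n_ensembles = res$n_members,
                 noise_sd_fraction = noise_sd_fraction),
            class = "imf_decomposition")
}

#' Suppress high-variance CCA components of the first IMF
#'
#' Canonical correlation analysis between the channels-by-time IMF1 matrix and
#' its delay-shifted copy orders components by lag-`delay` autocorrelation.
#' Components whose contributed variance exceeds
#' median + `iqr_mult` * IQR of the component variances are zeroed and the
#' matrix is rebuilt from the rest.
#'
#' @param imf1 channels x time matrix of first IMFs.
#' @param delay lag in samples (default 1).
#' @param iqr_mult multiplier on the IQR in the removal rule.
#' @return list with `cleaned` matrix, `cca` (an object with `correlations`,
#'   `unmixing`, `mixing`, `variances`), and `removed` component indices.
#' @export
cca_suppress_imf1 <- function(imf1, delay = 1, iqr_mult = 1.5) {
  X <- as.matrix(imf1)
  stopifnot(nrow(X) >= 2, ncol(X) >= nrow(X))
  mu <- rowMeans(X)
  Xc <- X - mu
  Tn <- ncol(Xc)
  Xa <- Xc[, 1:(Tn - delay), drop = FALSE]
  Xb <- Xc[, (1 + delay):Tn, drop = FALSE]
  sa <- svd(Xa); sb <- svd(Xb)
  tol <- max(sa$d) * 1e-8
  ra <- sum(sa$d > tol); rb <- sum(sb$d > tol)
  reduced <- ra < nrow(X) || rb < nrow(X)
  r <- min(ra, rb)
  Wa <- diag(1 / sa$d[1:r], r) %*% t(sa$u[, 1:r, drop = FALSE])
  Wb <- diag(1 / sb$d[1:r], r) %*% t(sb$u[, 1:r, drop = FALSE])
  M <- (Wa %*% Xa) %*% t(Wb %*% Xb)
  sv <- svd(M)
  cors <- pmin(pmax(sv$d, 0), 1)   # singular values of whitened cross-product
  W <- t(sv$u) %*% Wa                       # components x channels
  S <- W %*% Xc                             # components x time
  A <- sa$u[, 1:r, drop = FALSE] %*% diag(sa$d[1:r], r) %*% sv$u  # channels x comps
  var_s <- apply(S, 1, stats::var)
  contrib <- colSums(A^2) * var_s / nrow(X)
  med <- stats::median(contrib)
  iqr <- stats::IQR(contrib)
  removed <- which(contrib > med + iqr_mult * iqr)
  keep <- setdiff(seq_len(r), removed)
  cleaned <- A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  cca <- list(correlations = cors, unmixing = W, mixing = A,
              variances = contrib, rank_reduced = reduced)
  list(cleaned = cleaned, cca = cca, removed = removed)
}

#' Full denoising stage: ASR, then EEMD/CCA suppression of IMF1
#'
#' Runs ASR cleaning, extracts each EEG channel's first intrinsic mode
#' function by EEMD, removes high-variance CCA components of the IMF1 matrix,
#' and adds the cleaned IMF1 back to the IMF1-subtracted signal.
#'
#' @param raw an `eeg_recording`.
#' @param asr an `asr_model`, or NULL to skip ASR.
#' @param n_ensembles,noise_sd_fraction EEMD parameters (IMF1 only is
#'   extracted here).
#' @param delay,iqr_mult CCA parameters.
#' @return list with `raw` (cleaned), `log` (per-stage bookkeeping).
#' @export
apply_denoise <- function(raw, asr = NULL, n_ensembles = 20,
                          noise_sd_fraction = 0.1, delay = 1, iqr_mult = 1.5) {
  log <- list(stages = character(0))
  if (!is.null(asr)) {
    res <- asr_clean(raw, asr)
    raw <- res$raw
    log$asr <- res$log
    log$stages <- c(log$stages, "asr")
  }
  eeg <- channel_indices(raw, "EEG")
  X <- raw$data[eeg, , drop = FALSE]
  imf1 <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    dec <- eemd(X[i, ], n_ensembles = n_ensembles,
                noise_sd_fraction = noise_sd_fraction, max_imfs = 1)
    if (nrow(dec$imfs) >= 1) imf1[i, ] <- dec$imfs[1, ]
  }
  sup <- cca_suppress_imf1(imf1, delay = delay, iqr_mult = iqr_mult)
  raw$data[eeg, ] <- (X - imf1) + sup$cleaned
  log$eemd_cca <- list(removed_components = sup$removed,
                       n_components = length(sup$cca$variances))
  log$stages <- c(log$stages, "eemd", "cca")
  list(raw = raw, log = log)
}
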