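#' Downsample a recording
#'
#' Anti-alias filtered decimation for integer rate ratios (8th-order
#' Butterworth low-pass at 80% of the target Nyquist, applied zero-phase),
#' FFT resampling otherwise. Event times live on the seconds clock and are
#' unaffected.
#'
#' @param raw an `eeg_recording`.
#' @param target target sampling rate, Hz (must not exceed the current rate).
#' @return resampled `eeg_recording`.
#' @export
resample_recording <- function(raw, target) {
  if (target > raw$srate) stop("unsupported: upsampling requested")
  if (target == raw$srate) return(raw)
  factor <- raw$srate / target
  X <- raw$data
  if (abs(factor - round(factor)) < 1e-9) {
    factor <- round(factor)
    co <- butter_coeffs(8, 0.8 / factor, "low")
    idx <- seq(1, ncol(X), by = factor)
    Y <- matrix(0, nrow(X), length(idx))
    for (i in seq_len(nrow(X))) Y[i, ] <- filtfilt_iir(co$b, co$a, X[i, ])[idx]
  } else {
    n_new <- round(ncol(X) * target / raw$srate)
    Y <- t(apply(X, 1, fft_resample, n_new = n_new))
  }
  eeg_recording(Y, target, raw$labels, raw$kinds, raw$positions)
}

fft_resample <- function(x, n_new) {
  n <- length(x)
  X <- stats::fft(x)
  keep <- min(n, n_new)
  h <- floor(keep / 2)
  Y <- complex(n_new)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 0) Y[(n_new - h + 1):n_new] <- X[(n - h + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' High-pass filter a recording
#'
#' 4th-order Butterworth applied forward-backward (zero phase) to every
#' channel.
#'
#' @param raw an `eeg_recording`.
#' @param cutoff cutoff frequency, Hz.
#' @return filtered `eeg_recording`.
#' @export
highpass_filter <- function(raw, cutoff = 1) {
  stopifnot(cutoff < raw$srate / 2)
  co <- butter_coeffs(4, cutoff / (raw$srate / 2), "high")
  raw$data <- filtfilt_rows(raw$data, co$b, co$a)
  raw
}

#' Notch out mains interference
#'
#' Zero-phase biquad notch (+/- 1 Hz bandwidth by default) at the line
#' frequency and its first harmonic. With `line_freq = NULL` the recording is
#' returned unchanged.
#'
#' @param raw an `eeg_recording`.
#' @param line_freq mains frequency, Hz, or NULL.
#' @param bw notch bandwidth, Hz.
#' @return filtered `eeg_recording`.
#' @export
notch_line_noise <- function(raw, line_freq = NULL, bw = 2) {
  if (is.null(line_freq)) return(raw)
  stopifnot(line_freq < raw$srate / 2)
  for (f0 in c(line_freq, 2 * line_freq)) {
    if (f0 >= raw$srate / 2) next
    co <- notch_coeffs(f0, raw$srate, bw)
    raw$data <- filtfilt_rows(raw$data, co$b, co$a)
  }
  raw
}

#' Common median reference
#'
#' Subtracts, at every sample, the median across EEG channels from each EEG
#' channel. EMG and sync channels are untouched.
#'
#' @param raw an `eeg_recording`.
#' @return re-referenced `eeg_recording`.
#' @export
common_median_reference <- function(raw) {
  eeg <- channel_indices(raw, "EEG")
  stopifnot(length(eeg) >= 3)
  med <- col_median_cpp(raw$data[eeg, , drop = FALSE])
  raw$data[eeg, ] <- sweep(raw$data[eeg, , drop = FALSE], 2, med)
  raw
}

#' Average reference within a channel group
#'
#' @param raw an `eeg_recording`.
#' @param group "EEG" or "EMG".
#' @return re-referenced `eeg_recording`.
#' @export
average_reference <- function(raw, group = "EEG") {
  idx <- channel_indices(raw, group)
  stopifnot(length(idx) > 0)
  mu <- colMeans(raw$data[idx, , drop = FALSE])
  raw$data[idx, ] <- sweep(raw$data[idx, , drop = FALSE], 2, mu)
  raw
}

# k nearest neighbours per EEG channel, by position when available
neighbour_sets <- function(raw, k = 4) {
  eeg <- channel_indices(raw, "EEG")
  n <- length(eeg)
  have_pos <- !is.null(raw$positions) &&
    !anyNA(raw$positions[eeg, , drop = FALSE])
  lapply(seq_len(n), function(i) {
    if (have_pos) {
      p <- raw$positions[eeg, , drop = FALSE]
      d <- sqrt(colSums((t(p) - p[i, ])^2))
      order(d)[2:min(k + 1, n)]
    } else {
      cand <- setdiff(seq_len(n), i)
      cand[order(abs(cand - i))][seq_len(min(k, n - 1))]
    }
  })
}

#' Per-channel quality statistics
#'
#' Standard deviation, Pearson (non-excess) kurtosis over the full recording,
#' and the fraction of non-overlapping analysis windows in which the channel's
#' best absolute correlation with its neighbouring channels falls below
#' `corr_threshold`. EEG channels only.
#'
#' @param raw an `eeg_recording`.
#' @param window window length, s.
#' @param corr_threshold neighbour-correlation threshold.
#' @param n_neighbours neighbours per channel.
#' @return data.frame of class `channel_stats`.
#' @export
compute_channel_stats <- function(raw, window = 1, corr_threshold = 0.4,
                                  n_neighbours = 4) {
  eeg <- channel_indices(raw, "EEG")
  X <- raw$data[eeg, , drop = FALSE]
  wlen <- round(window * raw$srate)
  n_win <- floor(ncol(X) / wlen)
  if (n_win < 10) stop("recording too short: need at least 10 analysis windows")
  nbrs <- neighbour_sets(raw, n_neighbours)
  uncorr <- integer(nrow(X))
  for (w in seq_len(n_win)) {
    seg <- X[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
    C <- abs(suppressWarnings(stats::cor(t(seg))))
    C[!is.finite(C)] <- 0
    for (i in seq_len(nrow(X)))
      if (max(C[i, nbrs[[i]]]) < corr_threshold) uncorr[i] <- uncorr[i] + 1
  }
  sds <- apply(X, 1, stats::sd)
  kurt <- apply(X, 1, function(x) {
    x <- x - mean(x)
    mean(x^4) / mean(x^2)^2
  })
  out <- data.frame(channel = eeg, label = raw$labels[eeg], sd = sds,
                    kurtosis = kurt, uncorrelated_fraction = uncorr / n_win,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_stats", "data.frame")
  out
}

#' Flag bad channels by the three population criteria
#'
#' A channel is rejected when (a) its SD exceeds the cross-channel mean SD by
#' more than `sd_crit` SDs of the channel SDs, (b) its kurtosis exceeds the
#' mean by more than `kurt_crit` SDs of the channel kurtoses, or (c) it is
#' uncorrelated with its neighbours in more than `uncorr_crit` of the total
#' time; plus any manually listed channels.
#'
#' @param stats a `channel_stats` table.
#' @param manual integer channel indices to reject regardless.
#' @param sd_crit,kurt_crit,uncorr_crit the three thresholds (defaults 2, 5,
#'   0.01).
#' @return a `qc_report` list with the stats table, per-channel decisions and
#'   the retained count.
#' @export
flag_bad_channels <- function(stats, manual = integer(0), sd_crit = 2,
                              kurt_crit = 5, uncorr_crit = 0.01) {
  thr_sd <- mean(stats$sd) + sd_crit * stats::sd(stats$sd)
  thr_k <- mean(stats$kurtosis) + kurt_crit * stats::sd(stats$kurtosis)
  crit <- lapply(seq_len(nrow(stats)), function(i) {
    cr <- character(0)
    if (stats$sd[i] > thr_sd) cr <- c(cr, "high_sd")
    if (stats$kurtosis[i] > thr_k) cr <- c(cr, "high_kurtosis")
    if (stats$uncorrelated_fraction[i] > uncorr_crit) cr <- c(cr, "uncorrelated")
    if (stats$channel[i] %in% manual) cr <- c(cr, "manual")
    cr
  })
  bad <- which(lengths(crit) > 0)
  if (length(bad) == nrow(stats))
    stop("pipeline-halt: all channels rejected")
  rep <- list(stats = stats,
              bad_channels = stats$channel[bad],
              criteria = stats::setNames(crit[bad], stats$label[bad]),
              thresholds = c(sd = thr_sd, kurtosis = thr_k,
                             uncorrelated = uncorr_crit),
              retained = nrow(stats) - length(bad))
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d channels retained\n", x$retained,
              nrow(x$stats)))
  for (nm in names(x$criteria))
    cat("  rejected", nm, ":", paste(x$criteria[[nm]], collapse = ", "), "\n")
  invisible(x)
}

# Legendre polynomials P_1..P_L evaluated at x (vector), returned L x length(x)
legendre_table <- function(x, L) {
  P <- matrix(0, L, length(x))
  P[1, ] <- x
  if (L >= 2) P[2, ] <- 0.5 * (3 * x^2 - 1)
  if (L >= 3)
    for (l in 3:L)
      P[l, ] <- ((2 * l - 1) * x * P[l - 1, ] - (l - 1) * P[l - 2, ]) / l
  P
}

spherical_g <- function(cosang, m = 4, L = 50) {
  x <- pmin(pmax(as.numeric(cosang), -1), 1)
  P <- legendre_table(x, L)
  l <- seq_len(L)
  coef <- (2 * l + 1) / (l * (l + 1))^m
  matrix(colSums(P * coef) / (4 * pi), nrow = nrow(as.matrix(cosang)))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with Perrin-style spherical-spline estimates
#' from the remaining good EEG channels. Good channels are unchanged.
#'
#' @param raw an `eeg_recording` with positions for all EEG channels.
#' @param bad integer indices (into the recording) of channels to rebuild.
#' @param lambda ridge regularization added to the spline system.
#' @return `eeg_recording` with interpolated channels.
#' @export
interpolate_channels <- function(raw, bad, lambda = 1e-5) {
  if (length(bad) == 0) return(raw)
  eeg <- channel_indices(raw, "EEG")
  stopifnot(all(bad %in% eeg))
  if (length(bad) > length(eeg) / 2)
    stop("refusing to interpolate more than half of the EEG channels")
  if (is.null(raw$positions) || anyNA(raw$positions[eeg, ]))
    stop("positions required for interpolation")
  good <- setdiff(eeg, bad)
  P <- raw$positions
  unit <- P / sqrt(rowSums(P^2))
  cos_gg <- unit[good, , drop = FALSE] %*% t(unit[good, , drop = FALSE])
  cos_bg <- unit[bad, , drop = FALSE] %*% t(unit[good, , drop = FALSE])
  G <- spherical_g(cos_gg) + diag(lambda, length(good))
  Gb <- spherical_g(cos_bg)
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  rhs <- rbind(raw$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  C <- sol[seq_along(good), , drop = FALSE]
  c0 <- sol[length(good) + 1, ]
  raw$data[bad, ] <- Gb %*% C + matrix(c0, length(bad), ncol(raw$data), byrow = TRUE)
  raw
}
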