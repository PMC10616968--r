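# IIR filter design and zero-phase application.
# Butterworth low/high-pass via the analog prototype + bilinear transform;
# notch as an RBJ biquad. Coefficients were cross-checked against
# scipy.signal during development.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth filter coefficients
#'
#' @param n filter order.
#' @param Wn normalized cutoff in (0, 1), where 1 is the Nyquist frequency.
#' @param type "low" or "high".
#' @return list with numerator `b` and denominator `a`.
#' @export
butter_coeffs <- function(n, Wn, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, Wn > 0, Wn < 1)
  fs <- 2
  warped <- 2 * fs * tan(pi * Wn / fs)
  k <- seq_len(n)
  p0 <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # unit-circle prototype poles
  if (type == "low") {
    p <- warped * p0
    z <- complex(0)
    gain <- warped^n * Re(prod(-p0))               # unity DC gain
  } else {
    p <- warped / p0
    z <- rep(0 + 0i, n)
    gain <- 1
  }
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  gain_d <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * gain_d
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Biquad notch filter coefficients (constant-gain RBJ design)
#'
#' @param f0 notch centre frequency (Hz).
#' @param srate sampling rate (Hz).
#' @param bw notch bandwidth (Hz); default 2 (i.e. +/- 1 Hz).
#' @return list with `b` and `a`.
#' @export
notch_coeffs <- function(f0, srate, bw = 2) {
  w0 <- 2 * pi * f0 / srate
  Q <- f0 / bw
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# steady-state initial conditions (lfilter_zi construction)
filter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  a <- c(a, rep(0, nfilt - length(a)))
  b <- c(b, rep(0, nfilt - length(b)))
  b <- b / a[1]; a <- a / a[1]
  n <- nfilt - 1
  if (n == 0) return(numeric(0))
  A <- matrix(0, n, n)
  A[, 1] <- -a[-1]
  if (n > 1) A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n) - A, B))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forwards and backwards with odd extension padding and
#' steady-state initial conditions, so the result has zero phase distortion.
#'
#' @param b,a filter coefficients.
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  padlen <- min(3 * (ntaps - 1) * 4, n - 1)
  zi <- filter_zi(b, a)
  ext <- c(2 * x[1] - x[padlen + 1 - seq_len(padlen) + 1],
           x,
           2 * x[n] - x[n - seq_len(padlen)])
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

# apply filtfilt to a channel subset of a recording matrix
filtfilt_rows <- function(X, b, a, rows = seq_len(nrow(X))) {
  for (i in rows) X[i, ] <- filtfilt_iir(b, a, X[i, ])
  X
}

# |H(f)| of a digital filter at frequencies f (Hz)
freq_response <- function(b, a, f, srate) {
  w <- exp(-1i * 2 * pi * f / srate)
  num <- sapply(seq_along(b), function(k) b[k] * w^(k - 1))
  den <- sapply(seq_along(a), function(k) a[k] * w^(k - 1))
  if (is.null(dim(num))) { num <- sum(num); den <- sum(den) }
  else { num <- rowSums(num); den <- rowSums(den) }
  abs(num / den)
}
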