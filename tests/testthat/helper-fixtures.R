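# shared fixtures: everything is generated in code, no stored data

# epochs object straight from a trials x samples matrix (single channel)
make_epochs <- function(M, srate, tmin) {
  n <- ncol(M)
  structure(list(data = array(M, dim = c(nrow(M), 1, n)),
                 tmin = tmin, tmax = tmin + n / srate, srate = srate,
                 times = tmin + (seq_len(n) - 1) / srate,
                 event_times = numeric(nrow(M)), dropped = numeric(0)),
            class = "eeg_epochs")
}

# FFT analytic-signal envelope / phase
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) { h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1 } else h[2:((n + 1) / 2)] <- 2
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# band power via FFT periodogram
fft_band_power <- function(x, srate, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * srate / n
  sum(sp[f >= lo & f <= hi & f <= srate / 2])
}

# TFR epoch padding used when the full baseline must survive edge-trimming
tfr_pad <- function(fmin = 4, cycles = 3, support = 3.5) support * cycles / (2 * pi * fmin)

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
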