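#' Detect rising edges of a sync track
#'
#' Upward crossings of `low + threshold_fraction * (high - low)` with
#' sub-sample linear interpolation; crossings closer than `debounce` seconds
#' to the previous one are discarded. Set `falling = TRUE` to detect falling
#' edges instead.
#'
#' @param signal numeric vector (e.g. the 2 Hz square-wave sync channel).
#' @param srate sampling rate, Hz.
#' @param threshold_fraction crossing level as a fraction of the signal range.
#' @param debounce minimum edge separation, s.
#' @param falling detect falling edges.
#' @return numeric vector of edge times, s.
#' @export
detect_rising_edges <- function(signal, srate, threshold_fraction = 0.5,
                                debounce = 0.05, falling = FALSE) {
  if (falling) signal <- -signal
  lo <- stats::quantile(signal, 0.01, names = FALSE)
  hi <- stats::quantile(signal, 0.99, names = FALSE)
  if (hi - lo < 1e-12 * max(abs(c(lo, hi)), 1)) {
    warning("flat sync signal: no edges")
    return(numeric(0))
  }
  thr <- lo + threshold_fraction * (hi - lo)
  above <- signal >= thr
  idx <- which(!above[-length(above)] & above[-1])   # crossing between idx, idx+1
  if (length(idx) == 0) return(numeric(0))
  frac <- (thr - signal[idx]) / (signal[idx + 1] - signal[idx])
  times <- (idx - 1 + frac) / srate
  keep <- c(TRUE, diff(times) > debounce)
  times[keep]
}

#' Align an external clock to the recording clock
#'
#' Greedy nearest-neighbour matching of shared edges followed by a
#' least-squares linear fit external -> recording seconds.
#'
#' @param edges_ext edge times on the external clock, s.
#' @param edges_rec edge times on the recording clock, s.
#' @param max_unmatched tolerated unmatched fraction before erroring.
#' @return a `clock_map` list with `slope`, `intercept`, `residual_rms` (s)
#'   and `n_matched`, plus `apply(times)` via [map_times()].
#' @export
align_clocks <- function(edges_ext, edges_rec, max_unmatched = 0.2) {
  stopifnot(length(edges_ext) >= 10, length(edges_rec) >= 10)
  ext <- sort(edges_ext); rec <- sort(edges_rec)
  # coarse offset by median difference of overlapping heads, then greedy match
  k <- min(length(ext), length(rec))
  off <- stats::median(rec[seq_len(k)] - ext[seq_len(k)])
  tol <- 0.25 * stats::median(diff(rec))
  m_ext <- numeric(0); m_rec <- numeric(0)
  for (e in ext) {
    j <- which.min(abs(rec - (e + off)))
    if (abs(rec[j] - (e + off)) <= tol) {
      m_ext <- c(m_ext, e); m_rec <- c(m_rec, rec[j])
    }
  }
  if (length(m_ext) < (1 - max_unmatched) * length(ext))
    stop("alignment-failure: more than ", max_unmatched * 100,
         "% of external edges unmatched")
  fit <- stats::lm.fit(cbind(1, m_ext), m_rec)
  res <- sqrt(mean(fit$residuals^2))
  structure(list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
                 residual_rms = res, n_matched = length(m_ext)),
            class = "clock_map")
}

#' Map external-clock times through a clock map
#' @param map a `clock_map`.
#' @param times numeric times on the external clock, s.
#' @return times on the recording clock, s.
#' @export
map_times <- function(map, times) map$intercept + map$slope * times

#' Validate an occlusion-cycle event stream
#'
#' Checks that every offset follows its onset by the occlusion duration and
#' that inter-onset intervals lie in \[cycle, cycle + max_extra_delay\]. Out-of-
#' spec intervals are flagged (long gaps are interpreted as pauses), never
#' errors.
#'
#' @param events an `event_stream`.
#' @param config a `sim_config` (provides the nominal cycle).
#' @param tolerance timing tolerance, s.
#' @return list with `n_onsets`, `violations` (data.frame), `pauses`.
#' @export
validate_cycle <- function(events, config, tolerance = 0.02) {
  on <- events$onset[events$trial_type == "occlusion_onset"]
  off <- events$onset[events$trial_type == "occlusion_offset"]
  cycle <- config$occlusion_duration + config$clear_duration
  viol <- list()
  for (i in seq_along(on)) {
    j <- which(off > on[i] - tolerance)[1]
    if (is.na(j)) {
      viol[[length(viol) + 1]] <- data.frame(onset = on[i], kind = "missing_offset")
    } else if (off[j] < on[i]) {
      viol[[length(viol) + 1]] <- data.frame(onset = on[i], kind = "offset_before_onset")
    } else if (abs(off[j] - on[i] - config$occlusion_duration) > tolerance) {
      viol[[length(viol) + 1]] <- data.frame(onset = on[i], kind = "bad_occlusion_duration")
    }
  }
  pauses <- numeric(0)
  if (length(on) > 1) {
    ioi <- diff(on)
    bad <- which(ioi < cycle - tolerance |
                   ioi > cycle + config$max_extra_delay + tolerance)
    pauses <- on[bad]
    for (b in bad)
      viol[[length(viol) + 1]] <- data.frame(onset = on[b], kind = "pause_or_gap")
  }
  list(n_onsets = length(on),
       violations = if (length(viol)) do.call(rbind, viol)
                    else data.frame(onset = numeric(0), kind = character(0)),
       pauses = pauses)
}

#' Epoch a recording (or activation matrix) around events
#'
#' Extracts the half-open window [tmin, tmax) on the recording sample grid for
#' every event; events whose window leaves the recorded data are dropped and
#' logged.
#'
#' @param x an `eeg_recording`, or a channels x samples matrix (then `srate`
#'   is required).
#' @param events an `event_stream` or numeric vector of event times, s.
#' @param tmin,tmax epoch window relative to the event, s (defaults -0.5 and
#'   +2.0).
#' @param label restrict to events with this trial_type (default
#'   "occlusion_onset" when `events` is an `event_stream`).
#' @param srate sampling rate when `x` is a bare matrix.
#' @return an `eeg_epochs` object: `data` (trials x channels x samples),
#'   `times`, `tmin`, `tmax`, `srate`, `event_times`, `dropped`.
#' @export
epoch_recording <- function(x, events, tmin = -0.5, tmax = 2.0,
                            label = "occlusion_onset", srate = NULL) {
  if (inherits(x, "eeg_recording")) {
    X <- x$data; srate <- x$srate
  } else {
    X <- as.matrix(x)
    stopifnot(!is.null(srate))
  }
  times <- if (inherits(events, "event_stream") || is.data.frame(events))
    events$onset[events$trial_type == label] else as.numeric(events)
  n <- ncol(X)
  n_samp <- round((tmax - tmin) * srate)
  rel <- seq_len(n_samp) - 1
  usable <- logical(length(times))
  starts <- integer(length(times))
  for (i in seq_along(times)) {
    s0 <- round(times[i] * srate) + round(tmin * srate) + 1
    usable[i] <- s0 >= 1 && s0 + n_samp - 1 <= n
    starts[i] <- s0
  }
  if (!any(usable)) stop("zero usable events for epoching")
  keep <- which(usable)
  arr <- array(0, dim = c(length(keep), nrow(X), n_samp))
  for (k in seq_along(keep))
    arr[k, , ] <- X[, starts[keep[k]] + rel, drop = FALSE]
  structure(list(data = arr, tmin = tmin, tmax = tmax, srate = srate,
                 times = tmin + rel / srate,
                 event_times = times[keep], dropped = times[!usable]),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples, [%g, %g) s @ %g Hz\n",
              d[1], d[2], d[3], x$tmin, x$tmax, x$srate))
  invisible(x)
}
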