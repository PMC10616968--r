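#' Multichannel EEG recording container
#'
#' A lightweight container for a continuous multichannel recording: a
#' channels-by-samples numeric matrix in microvolts, with sampling rate,
#' channel labels, channel kinds and optional 3-D electrode positions.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz.
#' @param labels character vector of channel labels (defaults to CH1..CHn).
#' @param kinds character vector with one of "EEG", "EMG", "sync" per channel.
#' @param positions optional channels x 3 matrix of electrode positions (mm);
#'   rows for non-EEG channels may be NA.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, labels = NULL, kinds = NULL,
                          positions = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n_ch <- nrow(data)
  if (is.null(labels)) labels <- paste0("CH", seq_len(n_ch))
  if (is.null(kinds)) kinds <- rep("EEG", n_ch)
  stopifnot(length(labels) == n_ch, length(kinds) == n_ch,
            all(kinds %in% c("EEG", "EMG", "sync")), srate > 0)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == n_ch, ncol(positions) == 3)
  }
  structure(list(data = data, srate = srate, labels = labels, kinds = kinds,
                 positions = positions),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  tab <- table(x$kinds)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "),
      if (is.null(x$positions)) "| no positions" else "| positions present", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(raw) ncol(raw$data)

#' Indices of channels of a given kind
#' @param raw an `eeg_recording`.
#' @param kind one of "EEG", "EMG", "sync".
#' @return integer channel indices.
#' @export
channel_indices <- function(raw, kind = "EEG") which(raw$kinds == kind)

#' Drop channels from a recording
#' @param raw an `eeg_recording`.
#' @param idx integer indices of channels to remove.
#' @return the reduced `eeg_recording`.
#' @export
drop_channels <- function(raw, idx) {
  if (length(idx) == 0) return(raw)
  keep <- setdiff(seq_len(nrow(raw$data)), idx)
  eeg_recording(raw$data[keep, , drop = FALSE], raw$srate, raw$labels[keep],
                raw$kinds[keep],
                if (is.null(raw$positions)) NULL else raw$positions[keep, , drop = FALSE])
}

#' Ordered event stream
#'
#' Events are occlusion-cycle markers on a stated clock: `onset` in seconds,
#' `duration` in seconds and a `trial_type` label (`occlusion_onset` or
#' `occlusion_offset`).
#'
#' @param onset numeric vector of event times (s).
#' @param duration numeric vector of durations (s).
#' @param trial_type character vector of labels.
#' @return a data.frame of class `event_stream`, ordered by onset.
#' @export
event_stream <- function(onset, duration = 0, trial_type) {
  df <- data.frame(onset = as.numeric(onset),
                   duration = rep_len(as.numeric(duration), length(onset)),
                   trial_type = as.character(trial_type),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_stream", "data.frame")
  df
}
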