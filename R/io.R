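# Readers and writers: EDF/BDF (fixed-layout ASCII header + little-endian
# integer records), BIDS-shaped events TSV, electrode location text, ground
# truth and config JSON. Matrices that the reference tooling would put in
# HDF5 are written as TSV (no HDF5 library in the supported R stack).

pad_field <- function(x, width) {
  s <- strtrim(as.character(x), width)
  sprintf(paste0("%-", width, "s"), s)
}

num_field <- function(x, width = 8) pad_field(formatC(x, format = "g", digits = 6), width)

#' Write a recording to EDF or BDF
#'
#' Data are scaled to the channel's physical range and stored as 16-bit (EDF)
#' or 24-bit (BDF) little-endian integers in 1-second records; a trailing
#' partial second is zero-padded.
#'
#' @param raw an `eeg_recording` (data in microvolts).
#' @param path output file.
#' @param format "edf" or "bdf" (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(raw, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bdf$", path, ignore.case = TRUE)) "bdf" else "edf"
  stopifnot(format %in% c("edf", "bdf"))
  X <- raw$data
  n_ch <- nrow(X)
  spr <- round(raw$srate)                      # samples per 1-s record
  n_rec <- ceiling(ncol(X) / spr)
  if (ncol(X) < n_rec * spr)
    X <- cbind(X, matrix(0, n_ch, n_rec * spr - ncol(X)))
  dig_max <- if (format == "edf") 32767 else 8388607
  dig_min <- -dig_max - 1
  phys_max <- pmax(ceiling(apply(abs(X), 1, max)), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 * (n_ch + 1)
  if (format == "bdf") {
    writeBin(as.raw(255), con)
    writeChar("BIOSEMI", con, 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, 8, eos = NULL)
  }
  writeChar(pad_field("X X X X", 80), con, 80, eos = NULL)
  writeChar(pad_field("Startdate X X X X", 80), con, 80, eos = NULL)
  writeChar(pad_field("01.01.00", 8), con, 8, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, 8, eos = NULL)
  writeChar(pad_field(hdr_bytes, 8), con, 8, eos = NULL)
  writeChar(pad_field(if (format == "bdf") "24BIT" else "", 44), con, 44, eos = NULL)
  writeChar(pad_field(n_rec, 8), con, 8, eos = NULL)
  writeChar(pad_field(1, 8), con, 8, eos = NULL)
  writeChar(pad_field(n_ch, 4), con, 4, eos = NULL)
  kinds_dim <- ifelse(raw$kinds == "sync", "mV", "uV")
  for (i in seq_len(n_ch)) writeChar(pad_field(raw$labels[i], 16), con, 16, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field(raw$kinds[i], 80), con, 80, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("uV", 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(-phys_max[i]), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(phys_max[i]), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field(dig_min, 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field(dig_max, 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("HP:none", 80), con, 80, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field(spr, 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("", 32), con, 32, eos = NULL)
  scale <- (dig_max - dig_min) / (2 * phys_max)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(n_ch)) {
      d <- round((X[i, cols] + phys_max[i]) * scale[i]) + dig_min
      d <- pmin(pmax(d, dig_min), dig_max)
      if (format == "edf") {
        writeBin(as.integer(d), con, size = 2, endian = "little")
      } else {
        v <- as.integer(d)
        v[v < 0] <- v[v < 0] + 16777216L
        b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
        writeBin(as.raw(b), con)
      }
    }
  }
  invisible(path)
}

read_ascii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF or BDF recording
#'
#' @param path file path.
#' @return an `eeg_recording` (channel kinds recovered from the transducer
#'   field when present, else "EEG"; units microvolts).
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1)
  magic <- readChar(con, 7, useBytes = TRUE)
  format <- if (as.integer(first) == 255 && magic == "BIOSEMI") "bdf" else "edf"
  read_ascii(con, 160)                          # patient + recording
  read_ascii(con, 16)                           # date + time
  hdr_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  n_ch <- as.integer(read_ascii(con, 4))
  if (!is.finite(n_ch) || n_ch <= 0 || hdr_bytes != 256 * (n_ch + 1))
    stop("format error: corrupt header at offset 184 (signal count/size)")
  labels <- vapply(seq_len(n_ch), function(i) read_ascii(con, 16), "")
  trans <- vapply(seq_len(n_ch), function(i) read_ascii(con, 80), "")
  vapply(seq_len(n_ch), function(i) read_ascii(con, 8), "")
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) read_ascii(con, 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) read_ascii(con, 8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) read_ascii(con, 8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) read_ascii(con, 8), ""))
  vapply(seq_len(n_ch), function(i) read_ascii(con, 80), "")
  spr <- as.integer(vapply(seq_len(n_ch), function(i) read_ascii(con, 8), ""))
  vapply(seq_len(n_ch), function(i) read_ascii(con, 32), "")
  stopifnot(length(unique(spr)) == 1)
  srate <- spr[1] / rec_dur
  X <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(n_ch)) {
      if (format == "edf") {
        d <- readBin(con, "integer", spr[1], size = 2, endian = "little")
      } else {
        b <- as.integer(readBin(con, "raw", 3 * spr[1]))
        d <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
          65536 * b[seq(3, length(b), 3)]
        d[d >= 8388608] <- d[d >= 8388608] - 16777216
      }
      X[i, cols] <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  kinds <- ifelse(trans %in% c("EEG", "EMG", "sync"), trans, "EEG")
  eeg_recording(X, srate, labels, kinds)
}

#' Read a recording by format
#' @param path input file.
#' @param format "edf", "bdf", or "binary" (raw doubles + JSON sidecar
#'   `<path>.json`).
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "bdf", "binary")) {
  format <- match.arg(format)
  if (format %in% c("edf", "bdf")) return(read_recording_edf(path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  X <- matrix(readBin(con, "double", side$n_channels * side$n_samples),
              side$n_channels, side$n_samples)
  eeg_recording(X, side$srate, side$labels, side$kinds)
}

#' Write a recording as raw binary + JSON sidecar
#' @param raw an `eeg_recording`.
#' @param path output file (sidecar goes to `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_recording_binary <- function(raw, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(raw$data), con)
  close(con)
  jsonlite::write_json(list(n_channels = nrow(raw$data),
                            n_samples = ncol(raw$data), srate = raw$srate,
                            labels = raw$labels, kinds = raw$kinds),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write events to a tab-separated file (onset, duration, trial_type)
#' @param events an `event_stream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read events from a tab-separated file
#' @param path input path.
#' @return an `event_stream`.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  event_stream(df$onset, df$duration, df$trial_type)
}

#' Read whitespace-delimited electrode locations (label x y z)
#' @param path input path.
#' @return data.frame with label, x, y, z.
#' @export
read_electrode_locations <- function(path) {
  df <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  df
}

#' Serialize ground truth to JSON
#' @param gt a ground-truth list from the generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(list(
    effects = lapply(gt$effects, unclass),
    sources = lapply(gt$sources, unclass),
    bad_channels = gt$bad_channels,
    artifact_segments = gt$artifact_segments,
    event_schedule = as.data.frame(gt$event_schedule),
    mixing_matrix = gt$mixing_matrix), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a QC report to TSV (+ JSON decisions)
#' @param report a `qc_report`.
#' @param path_tsv stats table path; decisions go to `<path_tsv>.json`.
#' @return `path_tsv`, invisibly.
#' @export
write_qc_report <- function(report, path_tsv) {
  utils::write.table(as.data.frame(report$stats), path_tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(bad_channels = report$bad_channels,
                            criteria = report$criteria,
                            thresholds = as.list(report$thresholds),
                            retained = report$retained),
                       paste0(path_tsv, ".json"), auto_unbox = TRUE)
  invisible(path_tsv)
}
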