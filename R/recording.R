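#' EEG recording containers
#'
#' An `eeg_recording` holds one participant-trial's multichannel signal as a
#' channels-by-samples matrix in microvolts, together with the sampling rate
#' and channel labels. A `banded_recording` additionally records the frequency
#' band the signal has been restricted to and a per-sample validity mask used
#' for artifact exclusion.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sampling_rate sampling rate in Hz (positive scalar).
#' @param channel_names character vector of unique channel labels, one per row
#'   of `data`.
#' @param participant_id identifier for the participant.
#' @param trial_label trial label, conventionally one of `"FL-1"`, `"FL-2"`,
#'   `"MW-1"`, `"MW-2"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, sampling_rate, channel_names,
                          participant_id = "P01", trial_label = "FL-1") {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    stop("recording data must be numeric")
  }
  if (nrow(data) < 2L) {
    stop("a recording needs at least 2 channels")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar (Hz)")
  }
  if (ncol(data) < sampling_rate) {
    stop("recording must be at least 1 s long")
  }
  if (length(channel_names) != nrow(data)) {
    stop(sprintf("channel-count mismatch: %d labels for %d channels",
                 length(channel_names), nrow(data)))
  }
  if (anyDuplicated(channel_names)) {
    stop("channel_names must be unique")
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite values")
  }
  rownames(data) <- channel_names
  structure(
    list(
      participant_id = participant_id,
      trial_label = trial_label,
      sampling_rate = sampling_rate,
      channel_names = as.character(channel_names),
      data = data
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s / %s: %d channels x %d samples @ %g Hz\n",
              x$participant_id, x$trial_label,
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

# Canonical band table: name -> (low, high) Hz.
band_table <- function() {
  list(
    delta = c(1, 4),
    theta = c(4, 8),
    alpha = c(8, 13),
    beta  = c(13, 30),
    gamma = c(30, 80)
  )
}

#' Canonical frequency bands
#'
#' Returns the five canonical EEG band definitions used throughout the
#' pipeline: delta (1-4 Hz), theta (4-8), alpha (8-13), beta (13-30),
#' gamma (30-80).
#'
#' @return Named list of two-element numeric vectors `(low, high)` in Hz.
#' @export
eeg_bands <- function() band_table()

#' @rdname new_recording
#' @param rec an `eeg_recording`.
#' @param band band name, one of `names(eeg_bands())`.
#' @param valid_mask logical vector of length `ncol(rec$data)`; `TRUE` marks
#'   retained samples.
#' @export
new_banded_recording <- function(rec, band, valid_mask = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- band_table()
  if (!band %in% names(bands)) {
    stop(sprintf("unknown band '%s'; expected one of %s", band,
                 paste(names(bands), collapse = ", ")))
  }
  n <- ncol(rec$data)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (length(valid_mask) != n || !is.logical(valid_mask)) {
    stop("valid_mask must be logical with one entry per sample")
  }
  out <- unclass(rec)
  out$band <- band
  out$band_edges <- bands[[band]]
  out$valid_mask <- valid_mask
  class(out) <- c("banded_recording", "eeg_recording")
  out
}

#' @export
print.banded_recording <- function(x, ...) {
  cat(sprintf(
    "<banded_recording> %s / %s [%s %g-%g Hz]: %d ch x %d samples @ %g Hz (%.1f%% valid)\n",
    x$participant_id, x$trial_label, x$band, x$band_edges[1], x$band_edges[2],
    nrow(x$data), ncol(x$data), x$sampling_rate,
    100 * mean(x$valid_mask)))
  invisible(x)
}

#' Load a multichannel recording from disk
#'
#' Reads an EEG recording from one of three formats: `"edf"` (European Data
#' Format, 16-bit standard header), `"delimited"` (one column per channel with
#' a header row of channel names), or `"array"` (whitespace-delimited numeric
#' matrix, one row per channel, with a sidecar `<path>.meta` key-value file
#' supplying `sampling_rate` and `channel_names`).
#'
#' @param path path to the data file.
#' @param format one of `"edf"`, `"delimited"`, `"array"`.
#' @param sampling_rate sampling rate in Hz; required for `"delimited"`,
#'   ignored when the format carries its own rate.
#' @param channel_names optional channel labels overriding those in the file.
#' @param participant_id,trial_label metadata attached to the result.
#' @return An `eeg_recording`.
#' @export
load_recording <- function(path, format = c("delimited", "edf", "array"),
                           sampling_rate = NULL, channel_names = NULL,
                           participant_id = "P01", trial_label = "FL-1") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("cannot read recording: file '%s' does not exist", path))
  }
  loaded <- switch(format,
    delimited = load_delimited(path, sampling_rate),
    edf = read_edf(path),
    array = load_array(path)
  )
  if (!is.null(channel_names)) {
    if (length(channel_names) != nrow(loaded$data)) {
      stop(sprintf(
        "channel-count mismatch: %d labels supplied for %d channels in '%s'",
        length(channel_names), nrow(loaded$data), path))
    }
    loaded$channel_names <- channel_names
  }
  new_recording(loaded$data, loaded$sampling_rate, loaded$channel_names,
                participant_id = participant_id, trial_label = trial_label)
}

load_delimited <- function(path, sampling_rate) {
  if (is.null(sampling_rate)) {
    stop("sampling_rate must be supplied for delimited input")
  }
  df <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop(sprintf("non-numeric values in column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  list(data = t(as.matrix(df)), sampling_rate = sampling_rate,
       channel_names = colnames(df))
}

load_array <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop(sprintf("array format needs sidecar metadata file '%s'", meta_path))
  }
  meta <- read_config(meta_path)
  if (is.null(meta$sampling_rate)) {
    stop("sidecar metadata must contain sampling_rate")
  }
  mat <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(mat)) stop("non-numeric values in array file")
  labels <- if (!is.null(meta$channel_names)) {
    strsplit(meta$channel_names, ",[ ]*")[[1]]
  } else {
    paste0("ch", seq_len(nrow(mat)))
  }
  list(data = mat, sampling_rate = as.numeric(meta$sampling_rate),
       channel_names = labels)
}

# Minimal reader for 16-bit standard EDF. Assumes identical sampling rate on
# every signal and no annotation channels; sufficient for the 8-channel
# recordings this pipeline targets.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_records <- as.integer(substr(hdr, 237, 244))
  record_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1L) stop(sprintf("'%s' is not a parseable EDF", path))
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  field <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      substr(sig_hdr, offset * ns + (i - 1L) * width + 1L,
             offset * ns + i * width)
    }, character(1))
  }
  labels <- trimws(field(0L, 16L))
  phys_min <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16L + 80L + 8L) * ns + (i - 1L) * 8L + 1L,
           (16L + 80L + 8L) * ns + i * 8L), character(1))))
  phys_max <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16L + 80L + 8L + 8L) * ns + (i - 1L) * 8L + 1L,
           (16L + 80L + 8L + 8L) * ns + i * 8L), character(1))))
  dig_min <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16L + 80L + 8L + 16L) * ns + (i - 1L) * 8L + 1L,
           (16L + 80L + 8L + 16L) * ns + i * 8L), character(1))))
  dig_max <- as.numeric(trimws(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16L + 80L + 8L + 24L) * ns + (i - 1L) * 8L + 1L,
           (16L + 80L + 8L + 24L) * ns + i * 8L), character(1))))
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i)
    substr(sig_hdr, (16L + 80L + 8L + 32L + 80L) * ns + (i - 1L) * 8L + 1L,
           (16L + 80L + 8L + 32L + 80L) * ns + i * 8L), character(1))))
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports a single common sampling rate only")
  }
  rate <- spr[1] / record_dur
  out <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw_vals <- readBin(con, "integer", n = spr[s], size = 2L,
                          signed = TRUE, endian = "little")
      out[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        phys_min[s] + gain[s] * (raw_vals - dig_min[s])
    }
  }
  list(data = out, sampling_rate = rate, channel_names = labels)
}
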