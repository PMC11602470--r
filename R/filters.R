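#' Zero-phase FIR band-pass filtering into a canonical band
#'
#' Applies a windowed-Hamming finite-impulse-response band-pass filter,
#' forward and backward for zero phase, restricting the recording to one of
#' the five canonical EEG bands. The filter order follows the common
#' transition-bandwidth heuristic: the transition band is
#' `min(max(0.25 * low, 2), low)` Hz at the low edge and
#' `min(max(0.25 * high, 2), (rate/2 - high))` Hz at the high edge, and the
#' number of taps is `3.3 / (narrowest transition / rate)`, rounded up to odd.
#'
#' @param rec an `eeg_recording`.
#' @param band band name (see [eeg_bands()]).
#' @return A `banded_recording` with the same dimensions and an all-`TRUE`
#'   validity mask.
#' @export
bandpass_filter <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- band_table()
  if (!band %in% names(bands)) {
    stop(sprintf("unknown band '%s'", band))
  }
  edges <- bands[[band]]
  nyq <- rec$sampling_rate / 2
  if (edges[2] >= nyq) {
    stop(sprintf("band upper edge %g Hz is not below Nyquist (%g Hz)",
                 edges[2], nyq))
  }
  taps <- fir_bandpass_taps(edges[1], edges[2], rec$sampling_rate)
  filtered <- rec$data
  for (ch in seq_len(nrow(filtered))) {
    filtered[ch, ] <- filtfilt_fir(taps, rec$data[ch, ])
  }
  out <- rec
  out$data <- filtered
  new_banded_recording(out, band)
}

# Hamming-window FIR band-pass design for the given edges.
fir_bandpass_taps <- function(low, high, rate) {
  nyq <- rate / 2
  trans_low <- min(max(0.25 * low, 2), low)
  trans_high <- min(max(0.25 * high, 2), nyq - high)
  trans <- min(trans_low, trans_high)
  n <- ceiling(3.3 * rate / trans)
  if (n %% 2L == 0L) n <- n + 1L          # odd length -> integer group delay
  signal::fir1(n - 1L, c(low, high) / nyq, type = "pass",
               window = signal::hamming(n))
}

# Zero-phase application of an FIR filter with edge-reflection padding, which
# suppresses the start/end transients signal::filtfilt leaves on short
# segments.
filtfilt_fir <- function(taps, x) {
  n_pad <- min(length(taps) * 3L, length(x) - 1L)
  left <- 2 * x[1] - x[seq(n_pad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - n_pad)]
  padded <- c(left, x, right)
  y <- signal::filtfilt(signal::Ma(taps), padded)
  y[(n_pad + 1L):(n_pad + length(x))]
}

#' Mask amplitude-contaminated stretches
#'
#' Clears the validity mask wherever any channel's absolute amplitude exceeds
#' `threshold`, extending the exclusion by `pad` seconds on each side. The
#' signal itself is left untouched; downstream analysis drops any segment
#' overlapping a masked region rather than stitching across gaps.
#'
#' @param rec a `banded_recording`.
#' @param threshold amplitude threshold in microvolts (positive).
#' @param pad padding in seconds applied on each side of a suprathreshold
#'   sample.
#' @return The recording with an updated `valid_mask`.
#' @export
reject_by_amplitude <- function(rec, threshold = 100, pad = 0.25) {
  stopifnot(inherits(rec, "banded_recording"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive amplitude in microvolts")
  }
  if (pad < 0) stop("pad must be nonnegative")
  bad <- apply(abs(rec$data) > threshold, 2, any)
  if (any(bad)) {
    pad_n <- round(pad * rec$sampling_rate)
    idx <- which(bad)
    for (i in idx) {
      lo <- max(1L, i - pad_n)
      hi <- min(length(bad), i + pad_n)
      bad[lo:hi] <- TRUE
    }
  }
  rec$valid_mask <- rec$valid_mask & !bad
  rec
}
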