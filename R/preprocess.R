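# Preprocessing chain: band-pass -> z-score -> band-aligning decimation ->
# overlapping epochs. The fixed order matters: filtering first confines the
# signal to 3-30 Hz so the plain keep-every-kth decimation is alias-free,
# and z-scoring over the whole session removes between-assessment gain
# differences without touching the band ratios.

# Zero-phase Butterworth band-pass as a high-pass/low-pass cascade.
# Cascading two order-`order` sections is numerically safer than one
# transfer-function band-pass when the corners sit far apart relative to
# the sampling rate (3/125 here). Odd-reflection padding of several periods
# of the low corner suppresses the startup transient that zero initial
# conditions would otherwise leak into the output.
butter_bandpass <- function(x, low, high, fs, order = 4L) {
  n <- length(x)
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  pad <- min(n - 1L, as.integer(ceiling(12 * fs / low)))
  ext <- c(2 * x[1L] - rev(x[seq(2L, pad + 1L)]),
           x,
           2 * x[n] - rev(x[seq(n - pad, n - 1L)]))
  zero_phase <- function(e, flt) {
    y <- as.numeric(signal::filter(flt, e))
    rev(as.numeric(signal::filter(flt, rev(y))))
  }
  y <- zero_phase(zero_phase(ext, hp), lp)
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase band-pass filter of a recording
#'
#' Applies a 4th-order Butterworth band-pass (high-pass/low-pass cascade,
#' forward-backward for zero phase distortion) to every channel. Defaults
#' to the 3-30 Hz analysis band.
#'
#' @param recording an [eeg_recording()].
#' @param low,high corner frequencies in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Butterworth order of each cascade section.
#' @return a filtered `eeg_recording`.
#' @export
bandpass <- function(recording, low = 3, high = 30, order = 4L) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (!(low > 0 && low < high && high < fs / 2))
    abort_renyieeg(sprintf(
      "corner frequencies must satisfy 0 < low < high < fs/2 (fs = %g)", fs))
  out <- recording
  out$samples <- apply(recording$samples, 2L, butter_bandpass,
                       low = low, high = high, fs = fs, order = order)
  colnames(out$samples) <- recording$channel_labels
  out
}

#' Z-score normalize every channel of a recording
#'
#' Centers and scales each channel to mean 0, standard deviation 1 over the
#' entire recording (session-level scope: the normalization removes gain
#' and offset variation between assessments, not within-epoch structure).
#'
#' @param recording an [eeg_recording()].
#' @return a normalized `eeg_recording`.
#' @export
zscore <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  s <- recording$samples
  sds <- apply(s, 2L, sd)
  if (any(sds == 0))
    abort_renyieeg(sprintf(
      "constant channel(s) cannot be z-scored: %s",
      paste(recording$channel_labels[sds == 0], collapse = ", ")))
  out <- recording
  out$samples <- scale(s)[, , drop = FALSE]
  attr(out$samples, "scaled:center") <- NULL
  attr(out$samples, "scaled:scale") <- NULL
  colnames(out$samples) <- recording$channel_labels
  out
}

#' Decimate a band-limited recording for the wavelet band mapping
#'
#' Keeps every `factor`-th sample, dividing the sampling rate by `factor`.
#' At 250 Hz a 4-level db4 decomposition places detail level 1 at
#' 62.5-125 Hz, which matches no EEG rhythm; after x4 decimation to
#' 62.5 Hz the four detail levels span approximately 15.6-31.2 / 7.8-15.6 /
#' 3.9-7.8 / 2.0-3.9 Hz, i.e. the beta, alpha, theta and delta bands.
#' No anti-alias filter is applied: the input is expected to be already
#' band-limited below the new Nyquist (the 3-30 Hz band-pass guarantees
#' this for the default factor). If more than 1% of signal power lies above
#' the new Nyquist a warning is emitted, not an error.
#'
#' @param recording an [eeg_recording()] already band-limited below
#'   `fs / factor / 2`.
#' @param factor positive integer decimation factor.
#' @return an `eeg_recording` with `fs/factor` sampling rate.
#' @export
decimate_for_bands <- function(recording, factor = 4L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(factor) != 1L || factor < 1L || factor != round(factor))
    abort_renyieeg("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(recording)
  new_nyq <- recording$fs / factor / 2
  # cheap band-limitation check on the first channel periodogram
  x <- recording$samples[, 1L]
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(spec) - 1) / length(spec) * recording$fs
  half <- freqs <= recording$fs / 2
  p_hi <- sum(spec[half & freqs > new_nyq]) / sum(spec[half])
  if (is.finite(p_hi) && p_hi > 0.01)
    warning(sprintf(
      "%.1f%% of power above the new Nyquist (%g Hz); decimation will alias",
      100 * p_hi, new_nyq))
  out <- recording
  idx <- seq(1L, n_samples(recording), by = factor)
  out$samples <- recording$samples[idx, , drop = FALSE]
  out$fs <- recording$fs / factor
  out
}

#' Cut one channel into fixed-length overlapping epochs
#'
#' Produces the maximal set of full windows; a trailing partial window is
#' discarded rather than padded, because padding distorts band energies.
#' With `N` samples, window `w = window_s * fs` and hop
#' `h = w * (1 - overlap)`, the epoch count is `floor((N - w)/h) + 1`.
#'
#' @param recording an [eeg_recording()].
#' @param channel channel label (or index) to segment.
#' @param window_s window length in seconds (default 8 s).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return an object of class `epoch_set`: list with `epochs` (matrix, one
#'   column per epoch), `starts_s`, `window_s`, `overlap`, `fs`, `channel`.
#' @export
segment <- function(recording, channel = 1L, window_s = 8, overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.character(channel)) {
    ci <- match(channel, recording$channel_labels)
    if (is.na(ci))
      abort_renyieeg(sprintf("unknown channel '%s'; available: %s", channel,
                             paste(recording$channel_labels, collapse = ", ")))
  } else ci <- as.integer(channel)
  if (overlap < 0 || overlap >= 1)
    abort_renyieeg("overlap must be in [0, 1)")
  x <- recording$samples[, ci]
  w <- as.integer(round(window_s * recording$fs))
  h <- as.integer(round(w * (1 - overlap)))
  if (h < 1L) abort_renyieeg("hop is below one sample")
  n <- length(x)
  if (n < w)
    abort_renyieeg(sprintf(
      "recording (%d samples) shorter than one %g-s window (%d samples)",
      n, window_s, w))
  n_ep <- (n - w) %/% h + 1L
  starts <- (seq_len(n_ep) - 1L) * h
  epochs <- vapply(starts, function(s) x[(s + 1L):(s + w)], numeric(w))
  structure(list(epochs = epochs,
                 starts_s = starts / recording$fs,
                 window_s = window_s, overlap = overlap,
                 fs = recording$fs,
                 channel = recording$channel_labels[ci],
                 subject = recording$subject, session = recording$session),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs of %g s (%d samples) @ %g Hz, overlap %g, channel %s\n",
    ncol(x$epochs), x$window_s, nrow(x$epochs), x$fs, x$overlap, x$channel))
  invisible(x)
}

#' Run the fixed preprocessing chain on a recording
#'
#' Convenience wrapper applying, in this order: [bandpass()] -> [zscore()]
#' -> [decimate_for_bands()] -> [segment()] for one channel.
#'
#' @inheritParams segment
#' @inheritParams bandpass
#' @param factor decimation factor passed to [decimate_for_bands()].
#' @return an `epoch_set`.
#' @export
preprocess_channel <- function(recording, channel = 1L, low = 3, high = 30,
                               factor = 4L, window_s = 8, overlap = 0.5) {
  rec <- decimate_for_bands(zscore(bandpass(recording, low, high)), factor)
  segment(rec, channel, window_s, overlap)
}
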