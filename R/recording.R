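#' Construct a multi-channel EEG recording
#'
#' The basic container moved through the pipeline: a numeric matrix of
#' samples (rows = time, columns = channels) with a sampling rate and
#' channel labels, plus optional subject/session identifiers.
#'
#' @param samples numeric matrix, one column per channel (a vector is
#'   treated as a single channel).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of channel names; defaults to the
#'   four prefrontal 10-5 sites `AFp7, Fp1h, Fp2h, AFp8` truncated or
#'   extended to the number of columns.
#' @param subject,session optional identifiers carried through to output
#'   tables.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs,
                          channel_labels = NULL,
                          subject = NA, session = NA) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples) || nrow(samples) < 1L)
    abort_renyieeg("samples must be a non-empty numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_renyieeg("fs must be a single positive number")
  nc <- ncol(samples)
  if (is.null(channel_labels)) {
    defaults <- c("AFp7", "Fp1h", "Fp2h", "AFp8")
    channel_labels <- if (nc <= 4L) defaults[seq_len(nc)]
                      else c(defaults, paste0("ch", 5:nc))
  }
  if (length(channel_labels) != nc)
    abort_renyieeg("channel_labels length must match number of channels")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 subject = subject, session = session),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.na(x$subject) || !is.na(x$session))
    cat(sprintf("  subject: %s  session: %s\n", x$subject, x$session))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

n_samples <- function(rec) nrow(rec$samples)
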