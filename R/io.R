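# File formats: signal CSV, event TSV, session CSV, EDF (read, plus a
# minimal writer used to build fixtures), and the YAML pipeline config.
# All text files are UTF-8 with '.' decimal separator; lines starting with
# '#' are header comments (used to stamp the generating config hash).

#' Write / read the signal CSV dialect
#'
#' Column 1 is `time_s` (seconds from recording start, 0-based); remaining
#' columns are channels named in the header. Sampling must be uniform; on
#' read the rate is inferred from the median time delta and timestamps are
#' checked against it (max jitter 1e-6 s).
#'
#' @param recording an [eeg_recording()].
#' @param path file path.
#' @param digits significant digits for numeric fields.
#' @param comment optional character vector written as `# ` header lines.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns an `eeg_recording`.
#' @export
write_signal_csv <- function(recording, path, digits = 9, comment = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- n_samples(recording)
  dt <- data.table::data.table(
    time_s = signif((seq_len(n) - 1) / recording$fs, digits))
  for (ch in recording$channel_labels)
    dt[[ch]] <- signif(recording$samples[, ch], digits)
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  close(con)
  data.table::fwrite(dt, path, append = !is.null(comment), sep = ",",
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) abort_renyieeg(paste("no such file:", path))
  lines_total <- length(readLines(path, warn = FALSE))
  if (lines_total == 0L) abort_renyieeg(paste("empty file:", path))
  nf <- count.fields(path, sep = ",", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) abort_renyieeg(paste("no data rows in", path))
  expected <- nf[1L]
  bad <- which(nf != expected)
  if (length(bad))
    abort_renyieeg(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                           bad[1L], path, nf[bad[1L]], expected))
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (!"time_s" %in% names(dt))
    abort_renyieeg("signal CSV must have a time_s column")
  t <- dt$time_s
  if (length(t) < 2L) abort_renyieeg("need at least 2 samples")
  deltas <- diff(t)
  dt_med <- median(deltas)
  if (dt_med <= 0 || any(abs(deltas - dt_med) > 1e-6))
    abort_renyieeg("non-uniform timestamps (jitter above 1e-6 s)")
  fs <- 1 / dt_med
  # snap to an integer rate when within the timestamp print precision
  if (abs(fs - round(fs)) < 1e-4 * fs) fs <- round(fs)
  chans <- setdiff(names(dt), "time_s")
  eeg_recording(as.matrix(dt[chans]), fs, chans)
}

#' Write / read the oddball event TSV
#'
#' Tab-separated columns `time_s`, `kind` (`standard`/`deviant`/`press`)
#' and `modality`.
#'
#' @param log an `oddball_log` or compatible data.frame.
#' @param path file path.
#' @param comment optional `# ` header lines.
#' @return `read_event_tsv` returns a data.frame of events.
#' @export
write_event_tsv <- function(log, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  close(con)
  data.table::fwrite(as.data.frame(log)[c("time_s", "kind", "modality")],
                     path, append = !is.null(comment), sep = "\t",
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path) {
  if (!file.exists(path)) abort_renyieeg(paste("no such file:", path))
  ev <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("time_s", "kind", "modality")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    abort_renyieeg(paste("event TSV missing column(s):",
                         paste(miss, collapse = ", ")),
                   class = "renyieeg_schema_error")
  ev[order(ev$time_s), need]
}

#' Write / read the session CSV
#'
#' Columns: subject, session, sss, rt_audio_s, rt_visual_s, sleep_min
#' (reaction-time columns optional).
#'
#' @param table session data.frame.
#' @param path file path.
#' @param comment optional `# ` header lines.
#' @export
write_session_csv <- function(table, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  close(con)
  data.table::fwrite(as.data.frame(table), path,
                     append = !is.null(comment), sep = ",",
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) abort_renyieeg(paste("no such file:", path))
  data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format). A deliberately minimal reader for the
# standard continuous-recording case: one fixed record duration, uniform
# per-signal rates, 16-bit little-endian samples with linear
# digital-to-physical scaling. No installed R package parses EDF, so the
# byte-level access is done here directly.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a recording as a minimal EDF file
#'
#' Continuous EDF with 1-s data records and identical sampling rate for
#' all channels; physical units are microvolts. Intended for building
#' test fixtures and small exports; the digital quantization is 16-bit,
#' so round-tripping is exact only to the quantization step.
#'
#' @param recording an [eeg_recording()] whose `fs` and `duration` give an
#'   integer number of samples per 1-s record.
#' @param path output path.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    abort_renyieeg("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(recording$samples)
  n <- n_samples(recording)
  n_rec <- n %/% fs
  if (n_rec < 1L) abort_renyieeg("recording shorter than one 1-s EDF record")
  x <- recording$samples[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("synthetic subject", 80); wr("synthetic recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1L), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # re-read the printed physical extremes so scaling matches the header
  pmin_h <- as.numeric(format(pmin_, digits = 6))
  pmax_h <- as.numeric(format(pmax_, digits = 6))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[rows, i] - pmin_h[i]) / (pmax_h[i] - pmin_h[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into an EEG recording
#'
#' Supports continuous recordings whose requested channels share one
#' sampling rate. Samples are converted to physical units (microvolts)
#' using the per-signal linear scaling of the header.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep, in
#'   the requested order; defaults to all channels.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) abort_renyieeg(paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || n_rec < 0)
    abort_renyieeg("unsupported EDF: unknown number of data records")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (is.null(channels)) channels <- labels
  sel <- match(channels, labels)
  if (anyNA(sel))
    abort_renyieeg(sprintf("channel(s) %s not in file; available: %s",
                           paste(channels[is.na(sel)], collapse = ", "),
                           paste(labels, collapse = ", ")))
  if (length(unique(spr[sel])) != 1L)
    abort_renyieeg("requested channels have different sampling rates")
  fs <- spr[sel[1L]] / rec_dur
  out <- matrix(NA_real_, n_rec * spr[sel[1L]], length(sel))
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      j <- match(i, sel)
      if (!is.na(j))
        out[((r - 1L) * spr[i] + 1L):(r * spr[i]), j] <-
          (dig - dmin[i]) * gain[i] + pmin_[i]
    }
  }
  eeg_recording(out, fs, channels)
}

# ---------------------------------------------------------------------------
# Pipeline configuration (YAML)

#' Default pipeline configuration
#'
#' Nested key-value structure covering every tunable of the pipeline:
#' simulation (cohort geometry, trajectories come from [cohort_spec()]
#' defaults unless overridden), preprocessing (band, window, overlap,
#' decimation), entropy (wavelet, levels, q, normalization), behavioral
#' window, stats options and the master seed. Round-trips through YAML
#' identically.
#'
#' @param seed master seed.
#' @param ... named overrides of top-level sections (lists are merged
#'   shallowly).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = TRUE,
    cohort = list(n_subjects = 9L, duration_s = 300, fs = 250,
                  n_channels = 4L,
                  session_labels = c("Day1", "Day2", "Day3",
                                     "Day4A", "Day4B", "Day5"),
                  entropy_trajectory = c(0.657, 0.684, 0.661,
                                         0.737, 0.761, 0.841),
                  between_subject_sd = 0.15, within_subject_sd = 0.02,
                  noise_exponent = 1, bg_fraction = 0.3),
    preprocess = list(low_hz = 3, high_hz = 30, decimation = 4L,
                      window_s = 8, overlap = 0.5),
    entropy = list(wavelet = "db4", levels = 4L, q = 2, normalized = TRUE,
                   denoise = TRUE),
    behavioral = list(valid_window_s = c(0.1, 1.0)),
    stats = list(alpha = 0.05, report_channel = "Fp1h"),
    paths = list(output_dir = "renyieeg-output")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_renyieeg(paste("no such file:", path))
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(list(seed = raw$seed %||% 1L),
                                    raw[setdiff(names(raw), "seed")]))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
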