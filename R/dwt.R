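# Periodized orthonormal discrete wavelet transform (Daubechies-4).
#
# The decomposition filters are the standard db4 (length-8) pair. With the
# periodized boundary the one-level analysis operator is orthonormal, so
# Parseval holds exactly on even-length inputs and the inverse is the
# transpose. Odd-length inputs at any stage are extended by repeating the
# last sample before filtering (the usual periodization convention), which
# conserves energy only approximately - the reason dyadic-length epochs are
# preferred when exact energy bookkeeping matters.

DB4_LO <- c(-0.010597401785069032, 0.032883011666885197,
             0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.63088076792985892,
             0.71484657055291567, 0.23037781330889651)
DB4_HI <- c(-0.23037781330889651, 0.71484657055291567,
            -0.63088076792985892, -0.027983769416859854,
             0.18703481171909309, 0.030841381835560764,
            -0.032883011666885197, -0.010597401785069032)

wavelet_filters <- function(wavelet) {
  if (!identical(wavelet, "db4"))
    abort_renyieeg(sprintf("unsupported wavelet '%s' (only db4)", wavelet))
  list(lo = DB4_LO, hi = DB4_HI)
}

# One analysis step. 0-based convention (L = filter length, here 8):
#   a[k] = sum_m lo[m] * x[(2k + L/2 - m) mod N]
# which matches the periodized convention of standard wavelet toolboxes.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L) + 4L
  for (m in 0:7) {
    idx <- (base - m) %% n + 1L
    a <- a + lo[m + 1L] * x[idx]
    d <- d + hi[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# Transpose (synthesis) of dwt_step; `n_out` trims the sample appended for
# odd-length inputs.
idwt_step <- function(a, d, lo, hi, n_out = NULL) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L) + 4L
  for (m in 0:7) {
    idx <- (base - m) %% n + 1L
    x[idx] <- x[idx] + lo[m + 1L] * a + hi[m + 1L] * d
  }
  if (!is.null(n_out) && n_out < n) x <- x[seq_len(n_out)]
  x
}

#' Discrete wavelet decomposition of one epoch
#'
#' 4-level (by default) periodized db4 analysis. Detail levels 1..J halve
#' the frequency band at each step; at an effective sampling rate of
#' 62.5 Hz they correspond approximately to the beta, alpha, theta and
#' delta EEG bands, with the level-J approximation holding the residual
#' < 2 Hz content.
#'
#' @param epoch numeric vector of samples.
#' @param wavelet mother wavelet name; only `"db4"` is implemented.
#' @param levels decomposition depth J (default 4).
#' @return an object of class `wavelet_decomposition`: list with
#'   `detail` (list of detail coefficient vectors, level 1 first),
#'   `approx` (level-J approximation coefficients), `wavelet`, `levels`,
#'   `boundary_mode = "periodized"` and the original epoch length.
#' @export
dwt_decompose <- function(epoch, wavelet = "db4", levels = 4L) {
  if (!is.numeric(epoch) || length(epoch) < 2L^levels)
    abort_renyieeg(sprintf(
      "epoch of length %d too short for %d-level decomposition",
      length(epoch), levels))
  flt <- wavelet_filters(wavelet)
  detail <- vector("list", levels)
  lens <- integer(levels)
  a <- as.numeric(epoch)
  for (j in seq_len(levels)) {
    lens[j] <- length(a)
    st <- dwt_step(a, flt$lo, flt$hi)
    detail[[j]] <- st$d
    a <- st$a
  }
  structure(list(detail = detail, approx = a,
                 wavelet = wavelet, levels = as.integer(levels),
                 boundary_mode = "periodized",
                 input_lengths = lens, n = length(epoch)),
            class = "wavelet_decomposition")
}

#' Reconstruct an epoch from its wavelet decomposition
#'
#' Inverse of [dwt_decompose()]. On even-length-throughout (e.g. dyadic)
#' inputs the reconstruction is exact to numerical precision.
#'
#' @param decomp a `wavelet_decomposition`.
#' @return numeric vector of the original epoch length.
#' @export
dwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  flt <- wavelet_filters(decomp$wavelet)
  a <- decomp$approx
  for (j in rev(seq_len(decomp$levels)))
    a <- idwt_step(a, decomp$detail[[j]], flt$lo, flt$hi,
                   n_out = decomp$input_lengths[j])
  a
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d levels, %s boundary, n = %d\n",
              x$wavelet, x$levels, x$boundary_mode, x$n))
  cat("  detail lengths:", vapply(x$detail, length, 1L),
      " approx length:", length(x$approx), "\n")
  invisible(x)
}

#' In-band threshold denoising of detail coefficients
#'
#' Per detail level j the threshold is
#' `T_j = mean(|w_j|) + 2 * sd(|w_j|)` (population standard deviation of
#' the coefficient magnitudes), and every coefficient with `|w| > T_j`
#' (strict) is halved, keeping its sign. All other coefficients, and the
#' approximation, are untouched. Halving only ever shrinks magnitudes, so
#' total energy is non-increasing.
#'
#' @param decomp a `wavelet_decomposition`.
#' @return a `wavelet_decomposition` with denoised detail coefficients and
#'   an added `thresholds` field (one `T_j` per level).
#' @export
denoise_inband <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  thr <- numeric(decomp$levels)
  for (j in seq_len(decomp$levels)) {
    w <- decomp$detail[[j]]
    aw <- abs(w)
    mu <- mean(aw)
    sd_pop <- sqrt(mean((aw - mu)^2))
    thr[j] <- mu + 2 * sd_pop
    over <- aw > thr[j]
    w[over] <- w[over] / 2
    decomp$detail[[j]] <- w
  }
  decomp$thresholds <- thr
  decomp
}
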