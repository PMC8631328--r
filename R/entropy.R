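# Wavelet band energies and order-q Renyi entropy: the fatigue marker.

#' Wavelet band energies and relative energies
#'
#' `E_j = sum_k w_j(k)^2` for each detail level, and the relative energies
#' `p_j = E_j / sum_j E_j` over the four detail levels only. The
#' approximation band is excluded: at the 62.5 Hz effective rate the
#' details carry the beta/alpha/theta/delta rhythms, while the < 2 Hz
#' approximation is emptied by the 3 Hz high-pass and would only dilute
#' the profile.
#'
#' @param decomp a `wavelet_decomposition` with 4 detail levels.
#' @return an object of class `band_energy_profile`: list with `energies`,
#'   `relative` (both named by band, detail level 1 = beta first) and
#'   `band_names`.
#' @export
band_energies <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  if (decomp$levels != 4L)
    abort_renyieeg("band mapping requires exactly 4 detail levels")
  band_names <- c("beta", "alpha", "theta", "delta") # levels 1..4
  e <- vapply(decomp$detail, function(w) sum(w^2), numeric(1))
  names(e) <- band_names
  tot <- sum(e)
  if (tot <= 0)
    abort_renyieeg("degenerate profile: total detail energy is zero")
  structure(list(energies = e, relative = e / tot, band_names = band_names),
            class = "band_energy_profile")
}

#' @export
print.band_energy_profile <- function(x, ...) {
  cat("<band_energy_profile>\n")
  print(round(rbind(energy = x$energies, relative = x$relative), 4))
  invisible(x)
}

#' Order-q Renyi entropy of a relative-energy profile
#'
#' `RE = log(sum(p^q)) / (1 - q)`, natural log. With `normalized = TRUE`
#' the value is divided by `log(n)` so the uniform profile maps to 1 and a
#' one-hot profile to 0. The default `q = 2` weights concentrated profiles
#' strongly, which is what makes band flattening (fatigue) visible as an
#' entropy rise.
#'
#' @param relative numeric probability vector (non-negative, sums to 1
#'   within `1e-6`), or a `band_energy_profile`.
#' @param q entropic order, `q != 1`.
#' @param normalized divide by `log(length(relative))`?
#' @return a single dimensionless value; in `[0, 1]` when normalized.
#' @export
#' @examples
#' renyi_entropy(c(0.25, 0.25, 0.25, 0.25))        # 1
#' renyi_entropy(c(1, 0, 0, 0))                    # 0
#' renyi_entropy(c(0.4, 0.3, 0.2, 0.1))            # 0.8685
renyi_entropy <- function(relative, q = 2, normalized = TRUE) {
  if (inherits(relative, "band_energy_profile")) relative <- relative$relative
  if (any(relative < -1e-12))
    abort_renyieeg("relative energies must be non-negative")
  if (abs(sum(relative) - 1) > 1e-6)
    abort_renyieeg("relative energies must sum to 1")
  if (q == 1)
    abort_renyieeg("q = 1 (Shannon limit) is out of scope; use q != 1")
  p <- pmax(relative, 0)
  raw <- log(sum(p^q)) / (1 - q)
  if (normalized) raw / log(length(p)) else raw
}

#' Per-epoch and session-level wavelet Renyi entropy
#'
#' Applies [dwt_decompose()] -> [denoise_inband()] -> [band_energies()] ->
#' [renyi_entropy()] to every epoch (denoising thresholds are recomputed
#' per window) and aggregates to one session value as the arithmetic mean
#' of the per-epoch entropies.
#'
#' @param epochs an `epoch_set` from [segment()], or a numeric matrix with
#'   one epoch per column.
#' @param q entropic order (default 2).
#' @param normalized normalize to `[0, 1]`? (default TRUE)
#' @param wavelet,levels passed to [dwt_decompose()].
#' @param denoise apply the in-band threshold rule? (default TRUE)
#' @return an object of class `entropy_result`: list with `per_epoch`
#'   (numeric vector), `session_value` (their mean), `q`, `normalized`,
#'   `log_base = "e"`, plus epoch timing metadata when available.
#' @export
session_entropy <- function(epochs, q = 2, normalized = TRUE,
                            wavelet = "db4", levels = 4L, denoise = TRUE) {
  if (inherits(epochs, "epoch_set")) {
    mat <- epochs$epochs
    starts <- epochs$starts_s
    meta <- epochs[c("channel", "subject", "session")]
  } else if (is.matrix(epochs)) {
    mat <- epochs
    starts <- rep(NA_real_, ncol(mat))
    meta <- list(channel = NA, subject = NA, session = NA)
  } else abort_renyieeg("epochs must be an epoch_set or a matrix")
  if (ncol(mat) < 1L) abort_renyieeg("need at least one epoch")
  per <- numeric(ncol(mat))
  for (i in seq_len(ncol(mat))) {
    val <- tryCatch({
      dec <- dwt_decompose(mat[, i], wavelet = wavelet, levels = levels)
      if (denoise) dec <- denoise_inband(dec)
      renyi_entropy(band_energies(dec), q = q, normalized = normalized)
    }, renyieeg_error = function(e) {
      abort_renyieeg(sprintf("epoch %d: %s", i, conditionMessage(e)))
    })
    per[i] <- val
  }
  structure(list(per_epoch = per, session_value = mean(per),
                 q = q, normalized = normalized, log_base = "e",
                 starts_s = starts, channel = meta$channel,
                 subject = meta$subject, session = meta$session),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "<entropy_result> %d epochs, q = %g, %s: session value %.4f (range %.4f-%.4f)\n",
    length(x$per_epoch), x$q,
    if (x$normalized) "normalized" else "raw",
    x$session_value, min(x$per_epoch), max(x$per_epoch)))
  invisible(x)
}

#' Tidy per-epoch entropy table for one entropy result
#'
#' @param result an `entropy_result`.
#' @return data.frame with subject, session, channel, epoch_index,
#'   epoch_start_s and entropy columns.
#' @export
entropy_table <- function(result) {
  stopifnot(inherits(result, "entropy_result"))
  data.frame(subject = result$subject, session = result$session,
             channel = result$channel,
             epoch_index = seq_along(result$per_epoch),
             epoch_start_s = result$starts_s,
             entropy = result$per_epoch)
}
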