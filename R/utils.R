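#' Derive a reproducible substream seed
#'
#' Maps a master seed plus an arbitrary tuple of non-negative integer
#' counters (subject index, session index, channel index, purpose code, ...)
#' to a seed in `[0, 2^31 - 2]`. The map is a multiplicative congruential
#' mix evaluated exactly in double precision, so substreams for different
#' counter tuples are decoupled: adding or removing one subject never
#' changes the stream of another.
#'
#' @param master integer master seed.
#' @param ... non-negative integer counters identifying the substream.
#' @return an integer seed suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, 3, 2, 1)
substream_seed <- function(master, ...) {
  ks <- c(...)
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  # 69069 * (2^31 - 1) < 2^53: every product below is exact in doubles
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 1) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_substream <- function(seed, code) {
  withr::with_seed(seed, code)
}

# stop() with the condition class used across the package
abort_renyieeg <- function(msg, class = "renyieeg_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# MD5 of a config list via its canonical YAML serialization; used to stamp
# output tables so every artifact names the configuration that produced it.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
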