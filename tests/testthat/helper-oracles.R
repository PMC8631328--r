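# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: sums of squares by naive loops, the classic
# element-wise Greenhouse-Geisser formula, and plain-periodogram band
# power estimates.

# One-way within-subject ANOVA by explicit loops; epsilon via the classic
# covariance-element formula (not the eigenvalue route the package uses).
oracle_rm_oneway <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  g <- mean(Y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(Y[, j]) - g)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(Y[i, ]) - g)^2
  ss_tot <- sum((Y - g)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F_val <- (ss_cond / df1) / (ss_err / df2)
  S <- cov(Y)
  sbar <- mean(S)
  sbar_i <- rowMeans(S)
  num <- k^2 * (mean(diag(S)) - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(sbar_i^2) + k^2 * sbar^2)
  eps <- num / den
  eps <- min(max(eps, 1 / (k - 1)), 1)
  list(F = F_val, epsilon = eps,
       p = pf(F_val, eps * df1, eps * df2, lower.tail = FALSE),
       ss_cond = ss_cond, ss_err = ss_err)
}

# Two-way within-subject sums of squares by brute-force triple loops.
oracle_rm_twoway_ss <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  g <- mean(arr)
  m_s <- apply(arr, 1, mean); m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean); m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)
  ss <- list(A = 0, AS = 0, B = 0, BS = 0, AB = 0, ABS = 0)
  for (ai in seq_len(a)) ss$A <- ss$A + n * b * (m_a[ai] - g)^2
  for (bi in seq_len(b)) ss$B <- ss$B + n * a * (m_b[bi] - g)^2
  for (s in seq_len(n)) for (ai in seq_len(a))
    ss$AS <- ss$AS + b * (m_sa[s, ai] - m_s[s] - m_a[ai] + g)^2
  for (s in seq_len(n)) for (bi in seq_len(b))
    ss$BS <- ss$BS + a * (m_sb[s, bi] - m_s[s] - m_b[bi] + g)^2
  for (ai in seq_len(a)) for (bi in seq_len(b))
    ss$AB <- ss$AB + n * (m_ab[ai, bi] - m_a[ai] - m_b[bi] + g)^2
  for (s in seq_len(n)) for (ai in seq_len(a)) for (bi in seq_len(b))
    ss$ABS <- ss$ABS + (arr[s, ai, bi] - m_ab[ai, bi] - m_sa[s, ai] -
                          m_sb[s, bi] + m_a[ai] + m_b[bi] + m_s[s] - g)^2
  ss
}

# Relative power of `x` inside each of four frequency bands, from the raw
# periodogram.
oracle_rel_band_power <- function(x, fs, bands) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) / n * fs
  keep <- f <= fs / 2
  pw <- vapply(bands, function(b) sum(p[keep & f >= b[1] & f < b[2]]),
               numeric(1))
  pw / sum(pw)
}

# Long-format helper for the two-way ANOVA interface.
arr_to_long <- function(arr, fa = "A", fb = "B") {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  df <- expand.grid(subject = seq_len(n), A = seq_len(a), B = seq_len(b))
  df$value <- arr[cbind(df$subject, df$A, df$B)]
  names(df)[2:3] <- c(fa, fb)
  df
}

# Entropy of one generated subject/session cell through the default
# preprocessing chain (single channel).
cell_entropy <- function(spec, subject, session) {
  rec <- generate_eeg(spec, subject, session)
  session_entropy(preprocess_channel(rec, 1))$session_value
}

# Subjects x sessions entropy matrix for a whole (single-channel) cohort.
cohort_entropy_matrix <- function(spec) {
  t(sapply(seq_len(spec$n_subjects), function(subj)
    sapply(spec$session_labels, function(s) cell_entropy(spec, subj, s))))
}
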