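# Repeated-measures inference layer.
#
# Conventions: a one-factor within-subject table is a numeric matrix with
# one row per subject and one column per condition. The Greenhouse-Geisser
# correction is applied unconditionally to every within-subject effect
# (Mauchly's test is reported as a diagnostic only, never used as a gate);
# LSD post-hoc p-values are deliberately unadjusted, matching the named
# procedure.

# k x (k-1) matrix with orthonormal columns orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

# Greenhouse-Geisser epsilon from the covariance of q orthonormal contrast
# scores: eps = tr(V)^2 / (q * tr(V^2)), clamped into [1/q, 1].
gg_epsilon_from_contrast_cov <- function(V) {
  q <- nrow(V)
  lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (q * sum(lam^2))
  min(max(eps, 1 / q), 1)
}

#' Pivot a long table to a subjects-by-conditions matrix
#'
#' @param data data.frame in long format.
#' @param subject,condition,value column names.
#' @return numeric matrix with subjects as rows (named), conditions as
#'   columns in their factor-level (or first-appearance) order. Errors on
#'   missing or duplicated cells.
#' @export
as_within_matrix <- function(data, subject = "subject",
                             condition = "condition", value = "value") {
  miss <- setdiff(c(subject, condition, value), names(data))
  if (length(miss))
    abort_renyieeg(paste("missing column(s):", paste(miss, collapse = ", ")),
                   class = "renyieeg_schema_error")
  s <- data[[subject]]; cnd <- data[[condition]]
  s_lv <- if (is.factor(s)) levels(droplevels(s)) else unique(s)
  c_lv <- if (is.factor(cnd)) levels(droplevels(cnd)) else unique(cnd)
  Y <- matrix(NA_real_, length(s_lv), length(c_lv),
              dimnames = list(as.character(s_lv), as.character(c_lv)))
  idx <- cbind(match(s, s_lv), match(cnd, c_lv))
  if (anyDuplicated(idx))
    abort_renyieeg("duplicated (subject, condition) cells",
                   class = "renyieeg_schema_error")
  Y[idx] <- data[[value]]
  if (anyNA(Y))
    abort_renyieeg("incomplete design: missing (subject, condition) cells",
                   class = "renyieeg_schema_error")
  Y
}

check_within_matrix <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y) || nrow(Y) < 2L || ncol(Y) < 2L)
    abort_renyieeg("need a numeric subjects x conditions matrix, >= 2 each")
  if (anyNA(Y)) abort_renyieeg("within-subject table must be complete")
  Y
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of the orthonormal within-subject
#' contrasts is proportional to the identity. `W` is the ratio of the
#' geometric to the arithmetic mean (to the power `k - 1`) of the contrast
#' covariance eigenvalues; the p-value uses the standard chi-square
#' approximation. With `k = 2` sphericity holds trivially (`W = 1`,
#' `p = 1`). When `n <= k - 1` the contrast covariance is singular and the
#' test is undefined: the result carries `W = NA` and a diagnostic.
#'
#' @param Y numeric subjects x conditions matrix.
#' @return list with `W`, `chi2`, `df`, `p`, `diagnostic`.
#' @export
mauchly <- function(Y) {
  Y <- check_within_matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (k == 2L)
    return(list(W = 1, chi2 = 0, df = 0L, p = 1,
                diagnostic = "k = 2: sphericity holds trivially"))
  if (n <= k - 1L)
    return(list(W = NA_real_, chi2 = NA_real_,
                df = as.integer(k * (k - 1) / 2 - 1), p = NA_real_,
                diagnostic = sprintf(
                  "n = %d subjects cannot estimate a %d x %d contrast covariance",
                  n, k - 1L, k - 1L)))
  C <- orthonormal_contrasts(k)
  V <- t(C) %*% cov(Y) %*% C
  lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) <= .Machine$double.eps * max(lam))
    return(list(W = 0, chi2 = Inf, df = as.integer(k * (k - 1) / 2 - 1),
                p = 0, diagnostic = "singular contrast covariance"))
  W <- prod(lam) / (mean(lam))^(k - 1)
  mau_tail(W, k - 1L, n - 1L)
}

# Box's chi-square approximation (two terms) for -df*rho*log(W); pp is the
# number of orthonormal contrasts, nd the residual degrees of freedom.
mau_tail <- function(W, pp, nd) {
  rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nd)
  chi2 <- -nd * rho * log(W)
  dfc <- pp * (pp + 1) / 2 - 1
  w2 <- (pp + 2) * (pp - 1) * (pp - 2) *
    (2 * pp^3 + 6 * pp^2 + 3 * pp + 2) / (288 * (nd * pp * rho)^2)
  pr1 <- pchisq(chi2, dfc, lower.tail = FALSE)
  pr2 <- pchisq(chi2, dfc + 4, lower.tail = FALSE)
  list(W = W, chi2 = chi2, df = as.integer(dfc),
       p = min(max(pr1 + w2 * (pr2 - pr1), 0), 1),
       diagnostic = NA_character_)
}

rmanova_result <- function(F_val, df1, df2, eps, mau, ss_effect, ss_error,
                           effect = "condition") {
  p <- if (is.infinite(F_val)) 0
       else pf(F_val, eps * df1, eps * df2, lower.tail = FALSE)
  structure(list(effect = effect, F = F_val,
                 df_num = df1, df_den = df2,
                 epsilon_gg = eps,
                 df_num_gg = eps * df1, df_den_gg = eps * df2,
                 p = p,
                 mauchly_w = mau$W, mauchly_p = mau$p,
                 ss_effect = ss_effect, ss_error = ss_error),
            class = "rmanova_result")
}

#' @export
print.rmanova_result <- function(x, ...) {
  cat(sprintf(
    "<rmanova_result> %s: F(%.3f, %.3f) = %.3f, p = %.4g (GG eps = %.3f; Mauchly W = %s, p = %s)\n",
    x$effect, x$df_num_gg, x$df_den_gg, x$F, x$p, x$epsilon_gg,
    format(x$mauchly_w, digits = 3), format(x$mauchly_p, digits = 3)))
  invisible(x)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test from the explicit sums-of-squares decomposition:
#' `F = MS_condition / MS_(condition x subject)`. The Greenhouse-Geisser
#' epsilon is estimated from the orthonormal-contrast covariance and
#' applied unconditionally to both degrees of freedom; Mauchly's test is
#' attached as a diagnostic.
#'
#' @param Y numeric subjects x conditions matrix (see
#'   [as_within_matrix()] to pivot long data).
#' @return an `rmanova_result`: F, uncorrected df, `epsilon_gg`,
#'   corrected df, GG-corrected p, Mauchly W/p, sums of squares.
#' @export
rm_anova_oneway <- function(Y) {
  Y <- check_within_matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  g <- mean(Y)
  cm <- colMeans(Y); sm <- rowMeans(Y)
  ss_cond <- n * sum((cm - g)^2)
  resid <- Y - outer(sm, rep(1, k)) - matrix(cm, n, k, byrow = TRUE) + g
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F_val <- if (ss_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / df1) / (ss_err / df2)
  C <- orthonormal_contrasts(k)
  V <- t(C) %*% cov(Y) %*% C
  eps <- gg_epsilon_from_contrast_cov(V)
  rmanova_result(F_val, df1, df2, eps, mauchly(Y), ss_cond, ss_err)
}

#' Two-way fully-crossed within-subject ANOVA
#'
#' Both factors vary within subjects. Each effect (two main effects and
#' the interaction) is tested against its own subject-interaction error
#' term and carries its own Greenhouse-Geisser epsilon, estimated from the
#' covariance of that effect's orthonormal contrast scores (a Kronecker
#' contrast basis for the interaction).
#'
#' @param data long-format data.frame.
#' @param subject column naming the subject.
#' @param factors character vector of the two within-subject factor
#'   columns.
#' @param value column with the response.
#' @return named list of `rmanova_result` objects: one per factor plus
#'   `"<A>:<B>"` for the interaction.
#' @export
rm_anova_twoway <- function(data, subject = "subject",
                            factors = c("channel", "session"),
                            value = "value") {
  if (length(factors) != 2L)
    abort_renyieeg("exactly two within-subject factors are required")
  miss <- setdiff(c(subject, factors, value), names(data))
  if (length(miss))
    abort_renyieeg(paste("missing column(s):", paste(miss, collapse = ", ")),
                   class = "renyieeg_schema_error")
  fa <- data[[factors[1]]]; fb <- data[[factors[2]]]
  a_lv <- if (is.factor(fa)) levels(droplevels(fa)) else unique(fa)
  b_lv <- if (is.factor(fb)) levels(droplevels(fb)) else unique(fb)
  s_lv <- unique(data[[subject]])
  n <- length(s_lv); a <- length(a_lv); b <- length(b_lv)
  if (n < 2L || a < 2L || b < 2L)
    abort_renyieeg("need >= 2 subjects and >= 2 levels per factor")
  arr <- array(NA_real_, c(n, a, b))
  idx <- cbind(match(data[[subject]], s_lv), match(fa, a_lv),
               match(fb, b_lv))
  if (anyDuplicated(idx))
    abort_renyieeg("duplicated (subject, factor) cells",
                   class = "renyieeg_schema_error")
  arr[idx] <- data[[value]]
  if (anyNA(arr))
    abort_renyieeg("incomplete crossing of subject x factors",
                   class = "renyieeg_schema_error")

  g <- mean(arr)
  m_s <- apply(arr, 1, mean); m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean); m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)

  # cell matrix (subjects x ab) for contrast covariances
  Yc <- matrix(arr, n, a * b) # column order: a fastest, then b
  Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
  ua <- rep(1, a) / sqrt(a); ub <- rep(1, b) / sqrt(b)
  eps_for <- function(M) {
    V <- t(M) %*% cov(Yc) %*% M
    gg_epsilon_from_contrast_cov(V)
  }
  mau_for <- function(Ymat) mauchly(Ymat)

  res <- list()
  # main effect A
  ss_a <- n * b * sum((m_a - g)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      matrix(m_a, n, a, byrow = TRUE) + g)^2)
  Ma <- kronecker(ub, Ca) # (ab) x (a-1); kron index: b slow, a fast
  res[[factors[1]]] <- rmanova_result(
    if (ss_as == 0) { if (ss_a == 0) 0 else Inf }
    else (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
    a - 1, (a - 1) * (n - 1), eps_for(Ma), mau_for(m_sa),
    ss_a, ss_as, effect = factors[1])
  # main effect B
  ss_b <- n * a * sum((m_b - g)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      matrix(m_b, n, b, byrow = TRUE) + g)^2)
  Mb <- kronecker(Cb, ua)
  res[[factors[2]]] <- rmanova_result(
    if (ss_bs == 0) { if (ss_b == 0) 0 else Inf }
    else (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
    b - 1, (b - 1) * (n - 1), eps_for(Mb), mau_for(m_sb),
    ss_b, ss_bs, effect = factors[2])
  # interaction
  int_ab <- m_ab - outer(m_a, rep(1, b)) - matrix(m_b, a, b, byrow = TRUE) + g
  ss_ab <- n * sum(int_ab^2)
  resid <- arr
  for (s in seq_len(n)) for (ai in seq_len(a)) for (bi in seq_len(b))
    resid[s, ai, bi] <- arr[s, ai, bi] - m_ab[ai, bi] - m_sa[s, ai] -
      m_sb[s, bi] + m_a[ai] + m_b[bi] + m_s[s] - g
  ss_abs <- sum(resid^2)
  Mab <- kronecker(Cb, Ca)
  df1 <- (a - 1) * (b - 1); df2 <- df1 * (n - 1)
  # Mauchly on the interaction contrast scores directly
  Zab <- Yc %*% Mab
  mau_ab <- if (df1 == 1L || nrow(Zab) <= df1) {
    list(W = NA_real_, p = NA_real_)
  } else {
    lam <- eigen(cov(Zab), symmetric = TRUE, only.values = TRUE)$values
    if (min(lam) <= .Machine$double.eps * max(lam)) list(W = 0, p = 0)
    else mau_tail(prod(lam) / mean(lam)^df1, df1, n - 1L)
  }
  res[[paste(factors, collapse = ":")]] <- rmanova_result(
    if (ss_abs == 0) { if (ss_ab == 0) 0 else Inf }
    else (ss_ab / df1) / (ss_abs / df2),
    df1, df2, eps_for(Mab), mau_ab, ss_ab, ss_abs,
    effect = paste(factors, collapse = ":"))
  res
}

#' LSD post-hoc pairwise comparisons
#'
#' All `k(k-1)/2` paired t-tests between conditions, with unadjusted
#' p-values (Fisher's Least Significant Difference convention; the lack of
#' multiplicity control is intentional and should be stated when
#' reporting). A pair of identical conditions yields difference 0, t = 0,
#' p = 1.
#'
#' @param Y numeric subjects x conditions matrix.
#' @return data.frame: level_a, level_b, mean_diff, t, df, p.
#' @export
lsd_posthoc <- function(Y) {
  Y <- check_within_matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  labs <- colnames(Y); if (is.null(labs)) labs <- as.character(seq_len(k))
  pairs <- combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    d <- Y[, ij[1]] - Y[, ij[2]]
    md <- mean(d); sdd <- sd(d)
    if (sdd == 0) {
      t_val <- 0; p <- 1
      if (md != 0) { t_val <- Inf * sign(md); p <- 0 }
    } else {
      t_val <- md / (sdd / sqrt(n))
      p <- 2 * pt(-abs(t_val), n - 1)
    }
    c(mean_diff = md, t = t_val, df = n - 1, p = p)
  })
  data.frame(level_a = labs[pairs[1, ]], level_b = labs[pairs[2, ]],
             t(out))
}

#' Pearson correlation with t-distribution p-value
#'
#' Thin wrapper over [stats::cor.test()] with explicit degenerate-input
#' checks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort_renyieeg("x and y must have equal length >= 3")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort_renyieeg("fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    abort_renyieeg("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
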