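# Repeated-measures inference: every statistic is checked against an
# independent route (naive-loop sums of squares, the element-wise GG
# formula, stats::aov / stats::mauchly.test, paired t).

test_that("one-way RM-ANOVA matches the brute-force oracle exactly", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:12, 1); k <- sample(3:7, 1)
    Y <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k)
    r <- rm_anova_oneway(Y)
    o <- oracle_rm_oneway(Y)
    expect_equal(r$F, o$F, tolerance = 1e-9)
    expect_equal(r$epsilon_gg, o$epsilon, tolerance = 1e-9)
    expect_equal(r$p, o$p, tolerance = 1e-9)
  }
})

test_that("one-way RM-ANOVA agrees with stats::aov on a random table", {
  set.seed(42)
  Y <- matrix(rnorm(6 * 4), 6, 4)
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(1:6, 4)),
                   cond = factor(rep(1:4, each = 6)))
  fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  f_aov <- fit[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(rm_anova_oneway(Y)$F, f_aov, tolerance = 1e-9)
})

test_that("k = 2 reduces to the squared paired t statistic", {
  set.seed(43)
  for (i in 1:10) {
    Y <- matrix(rnorm(16), 8, 2)
    r <- rm_anova_oneway(Y)
    t2 <- unname(t.test(Y[, 1], Y[, 2], paired = TRUE)$statistic^2)
    expect_equal(r$F, t2, tolerance = 1e-9)
    expect_equal(r$epsilon_gg, 1)
  }
})

test_that("identical conditions give F = 0; zero error is diagnosed", {
  Y <- matrix(rnorm(8), 8, 1)[, c(1, 1, 1)]
  r <- rm_anova_oneway(Y)
  expect_equal(r$F, 0)
  # purely additive subject + condition structure (values chosen so all
  # cell means are exact in binary): error SS = 0 exactly, effect > 0
  Y2 <- outer(c(1, 2, 3, 4), rep(1, 4)) + outer(rep(1, 4), c(1, 2, 3, 6))
  r2 <- rm_anova_oneway(Y2)
  expect_true(is.infinite(r2$F))
  expect_equal(r2$p, 0)
})

test_that("epsilon is 1 for an exactly spherical contrast covariance", {
  set.seed(44)
  n <- 12; k <- 5
  C <- renyieeg:::orthonormal_contrasts(k)
  Z <- scale(matrix(rnorm(n * (k - 1)), n), scale = FALSE)
  Zw <- Z %*% solve(chol(cov(Z))) # empirically whitened: cov = I
  Y <- Zw %*% t(C) + rnorm(n)     # subject offsets do not affect contrasts
  r <- rm_anova_oneway(Y)
  expect_equal(r$epsilon_gg, 1, tolerance = 1e-9)
  # and always within the theoretical bounds
  for (i in 1:20) {
    Y <- matrix(rnorm(8 * k), 8, k)
    e <- rm_anova_oneway(Y)$epsilon_gg
    expect_gte(e, 1 / (k - 1)); expect_lte(e, 1)
  }
})

test_that("Mauchly matches stats::mauchly.test and its edge cases", {
  set.seed(45)
  Y <- matrix(rnorm(10 * 4), 10, 4)
  m <- mauchly(Y)
  ref <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(m$W, unname(ref$statistic), tolerance = 1e-9)
  # the reference uses a slight variant of the Box w2 term; agreement on
  # the p-value is to ~1e-3, exact on W
  expect_equal(m$p, ref$p.value, tolerance = 1e-3)
  # k = 2: trivially spherical
  m2 <- mauchly(Y[, 1:2])
  expect_equal(m2$W, 1); expect_equal(m2$p, 1)
  # one dominant direction: W near 0
  base <- rnorm(10, sd = 4)
  Y3 <- outer(base, c(1, -1, 0.5, -0.5)) + matrix(rnorm(40, sd = 1e-3), 10)
  expect_lt(mauchly(Y3)$W, 1e-4)
  # too few subjects: diagnostic, not a crash
  m4 <- mauchly(matrix(rnorm(12), 3, 4))
  expect_true(is.na(m4$W))
  expect_match(m4$diagnostic, "subjects")
})

test_that("Mauchly p-values are roughly uniform under sphericity", {
  set.seed(46)
  ps <- replicate(200, mauchly(matrix(rnorm(20 * 3), 20, 3))$p)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
})

test_that("two-way RM-ANOVA matches the brute-force SS decomposition", {
  set.seed(47)
  for (i in 1:5) {
    arr <- array(rnorm(9 * 4 * 6), c(9, 4, 6))
    ss <- oracle_rm_twoway_ss(arr)
    res <- rm_anova_twoway(arr_to_long(arr, "channel", "session"),
                           factors = c("channel", "session"))
    f_a <- (ss$A / 3) / (ss$AS / (3 * 8))
    f_b <- (ss$B / 5) / (ss$BS / (5 * 8))
    f_ab <- (ss$AB / 15) / (ss$ABS / (15 * 8))
    expect_equal(res$channel$F, f_a, tolerance = 1e-8)
    expect_equal(res$session$F, f_b, tolerance = 1e-8)
    expect_equal(res$`channel:session`$F, f_ab, tolerance = 1e-8)
    expect_equal(res$channel$ss_effect, ss$A, tolerance = 1e-8)
    expect_equal(res$`channel:session`$ss_error, ss$ABS, tolerance = 1e-8)
  }
})

test_that("two-way degenerate structures behave as constructed", {
  set.seed(48)
  n <- 7; a <- 3; b <- 4
  subj <- rnorm(n); tim <- rnorm(b)
  # constant in factor A, additive subject + B: A effect and interaction 0
  arr <- array(0, c(n, a, b))
  for (s in 1:n) for (ai in 1:a) for (bi in 1:b)
    arr[s, ai, bi] <- subj[s] + tim[bi]
  res <- rm_anova_twoway(arr_to_long(arr, "A", "B"), factors = c("A", "B"))
  expect_equal(res$A$F, 0)
  expect_equal(res$`A:B`$ss_effect, 0, tolerance = 1e-20)
})

test_that("F and p are invariant to subject and label permutations", {
  set.seed(49)
  Y <- matrix(rnorm(8 * 5), 8, 5)
  r1 <- rm_anova_oneway(Y)
  r2 <- rm_anova_oneway(Y[sample(8), ])     # permute subjects
  perm <- sample(5)
  r3 <- rm_anova_oneway(Y[, perm])          # permute conditions
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$F, r3$F, tolerance = 1e-12)
  expect_equal(r1$epsilon_gg, r3$epsilon_gg, tolerance = 1e-12)
})

test_that("LSD post-hoc enumerates pairs with unadjusted paired t-tests", {
  set.seed(50)
  Y <- matrix(rnorm(9 * 6), 9, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  ph <- lsd_posthoc(Y)
  expect_equal(nrow(ph), 15L) # 6 * 5 / 2
  # internal consistency: t^2 equals the k = 2 RM-ANOVA F for that pair
  for (r in c(1, 7, 15)) {
    i <- match(ph$level_a[r], colnames(Y))
    j <- match(ph$level_b[r], colnames(Y))
    expect_equal(ph$t[r]^2, rm_anova_oneway(Y[, c(i, j)])$F,
                 tolerance = 1e-9)
    tt <- t.test(Y[, i], Y[, j], paired = TRUE)
    expect_equal(ph$p[r], tt$p.value, tolerance = 1e-12)
  }
  # identical conditions: difference 0, p = 1
  Y2 <- cbind(Y[, 1], Y[, 1], Y[, 2])
  ph2 <- lsd_posthoc(Y2)
  expect_equal(ph2$mean_diff[1], 0)
  expect_equal(ph2$p[1], 1)
})

test_that("Pearson correlation matches hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1, tolerance = 1e-12)
  r <- pearson(x, c(1, 3, 2, 4))
  expect_equal(r$r, 0.8, tolerance = 1e-12)
  expect_equal(r$p, cor.test(x, c(1, 3, 2, 4))$p.value, tolerance = 1e-12)
  expect_error(pearson(x, rep(1, 4)), "constant")
  expect_error(pearson(1:2, 1:2), "length")
})

test_that("long-to-wide pivot validates schema and completeness", {
  df <- data.frame(subject = rep(1:3, each = 2),
                   condition = rep(c("a", "b"), 3),
                   value = rnorm(6))
  Y <- as_within_matrix(df)
  expect_equal(dim(Y), c(3L, 2L))
  expect_equal(Y["2", "b"], df$value[4])
  expect_error(as_within_matrix(df[-1, ]), "incomplete",
               class = "renyieeg_schema_error")
  expect_error(as_within_matrix(df[c(1, 1, 2:6), ]), "duplicated",
               class = "renyieeg_schema_error")
  expect_error(as_within_matrix(df[, -3]), "missing column",
               class = "renyieeg_schema_error")
})
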