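# Paired tests, correlation, ICC and the permutation machinery.

test_that("paired t-test matches the closed-form statistic", {
  expect_equal(paired_ttest(1:5, 1:5)$statistic, 0)
  expect_equal(paired_ttest(1:5, 1:5)$p_value, 1)
  set.seed(2)
  a <- rnorm(9); b <- a - 1 - rnorm(9, sd = 0.01)
  r <- paired_ttest(a, b)
  expect_gt(abs(r$statistic), 10)
  expect_lt(r$p_value, 0.01)
  for (i in 1:10) {
    a <- rnorm(9); b <- rnorm(9)
    d <- a - b
    t_oracle <- mean(d) / (stats::sd(d) / sqrt(9))
    r <- paired_ttest(a, b)
    expect_equal(r$statistic, t_oracle, tolerance = 1e-10)
    expect_equal(r$df, 8)
    expect_equal(r$p_value, 2 * stats::pt(-abs(t_oracle), 8), tolerance = 1e-10)
  }
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("Wilcoxon signed-rank exact p equals full sign-pattern enumeration", {
  # all-positive differences, n = 9: V = 45, one-sided exact p = 1/2^9
  b <- rnorm(9)
  a <- b + (1:9) / 10 # distinct positive differences, untied ranks
  r <- wilcoxon_signed_rank(a, b, alternative = "greater")
  expect_equal(r$statistic, 45)
  expect_equal(r$p_value, 1 / 2^9)
  expect_true(r$exact)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  # enumeration oracle over all 2^9 sign patterns
  set.seed(6)
  for (i in 1:5) {
    d <- rnorm(9)
    V <- sum(rank(abs(d))[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 9)))
    r_abs <- rank(abs(d))
    null_V <- signs %*% r_abs
    p_ge <- mean(null_V >= V)
    p_le <- mean(null_V <= V)
    p_two <- min(1, 2 * min(p_ge, p_le))
    got <- wilcoxon_signed_rank(d, rep(0, 9))
    expect_equal(got$statistic, V)
    expect_equal(got$p_value, p_two, tolerance = 1e-12)
  }
})

test_that("Pearson correlation and its t-based p match the formula oracle", {
  a <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_correlation(a, -a)$r, -1)
  set.seed(7)
  x <- rnorm(9); y <- rnorm(9)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt(7 / (1 - r_oracle^2))
  got <- pearson_correlation(x, y)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_oracle), 7), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("ICC(2,1) matches the ANOVA decomposition and is symmetric", {
  expect_equal(icc_single(sin(1:20), sin(1:20)), 1)
  # hand table: ANOVA-decomposition oracle via aov mean squares
  x <- c(9, 6, 8, 7, 10)
  y <- c(8, 5, 9, 6, 9)
  df <- data.frame(
    score = c(x, y),
    target = factor(rep(1:5, 2)),
    rater = factor(rep(1:2, each = 5))
  )
  ms <- summary(stats::aov(score ~ target + rater, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 5)
  expect_equal(icc_single(x, y), icc_oracle, tolerance = 1e-10)
  expect_equal(icc_single(x, y), icc_single(y, x), tolerance = 1e-14)
  # consistency variant
  icc3_oracle <- (msr - mse) / (msr + mse)
  expect_equal(icc_single(x, y, type = "consistency"), icc3_oracle, tolerance = 1e-10)
  # unrelated series: near-zero ICC
  set.seed(10)
  vals <- replicate(20, icc_single(rnorm(769), rnorm(769)))
  expect_lt(max(abs(vals)), 0.2)
  expect_error(icc_single(rep(1, 20), rep(1, 20)), "degenerate")
})

test_that("ICC permutation test: exact-agreement pairs reach the minimal p", {
  set.seed(12)
  pairs <- lapply(1:5, function(s) {
    w <- rnorm(50)
    list(a = w, b = w)
  })
  r <- icc_permutation_test(pairs, n_perm = 99, seed = 1)
  expect_equal(r$mean_icc, 1)
  expect_equal(r$p_value, 1 / 100)
  # determinism under a fixed seed
  r2 <- icc_permutation_test(pairs, n_perm = 99, seed = 1)
  expect_identical(r$p_value, r2$p_value)
  expect_identical(r$null_mean_iccs, r2$null_mean_iccs)
})

test_that("ICC permutation p-values are calibrated under the null", {
  set.seed(13)
  pvals <- replicate(200, {
    pairs <- lapply(1:6, function(s) list(a = rnorm(30), b = rnorm(30)))
    icc_permutation_test(pairs, n_perm = 199,
                         seed = sample.int(1e6, 1))$p_value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("TF permutation test finds a banded offset and nothing under the null", {
  set.seed(15)
  S <- 9; FQ <- 6; TM <- 8
  base <- array(rnorm(S * FQ * TM), c(S, FQ, TM))
  noise <- array(rnorm(S * FQ * TM, sd = 0.5), c(S, FQ, TM))
  shifted <- base + noise
  shifted[, 2:3, ] <- shifted[, 2:3, ] + 2 # offset band at 2x within-subject sd
  r <- tf_permutation_test(shifted, base, n_perm = 499, seed = 3)
  expect_true(all(dim(r$p_map) == c(FQ, TM)))
  expect_gt(mean(r$p_map[2:3, ] < 0.05), 0.9)
  expect_lt(mean(r$p_map[-(2:3), ] < 0.05), 0.3)
  # identical inputs: zero-difference convention gives p = 1 everywhere
  same <- tf_permutation_test(base, base, n_perm = 99, seed = 4)
  expect_true(all(same$p_map == 1))
  expect_true(all(same$t_map == 0))
  expect_error(
    tf_permutation_test(base, base[, 1:3, , drop = FALSE], n_perm = 9, seed = 1),
    "grids"
  )
})

test_that("TF permutation type-I error is near alpha under exchangeability", {
  set.seed(16)
  hits <- replicate(200, {
    A <- array(rnorm(8 * 4 * 5), c(8, 4, 5))
    B <- array(rnorm(8 * 4 * 5), c(8, 4, 5))
    r <- tf_permutation_test(A, B, n_perm = 199, seed = sample.int(1e6, 1))
    mean(r$p_map < 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("grand averaging is the naive element-wise mean", {
  v <- rnorm(10)
  expect_equal(grand_average(list(v)), v)
  expect_equal(grand_average(list(v, -v)), rep(0, 10))
  set.seed(18)
  ms <- lapply(1:7, function(i) matrix(rnorm(12), 3))
  got <- grand_average(ms)
  expected <- matrix(0, 3, 4)
  for (m in ms) expected <- expected + m / 7
  expect_equal(got, expected, tolerance = 1e-12)
  expect_error(grand_average(list(rnorm(3), rnorm(4))), "mismatch")
})
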