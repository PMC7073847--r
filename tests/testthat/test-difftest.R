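make_rho <- function(p, value = 0, names = paste0("V", seq_len(p))) {
  m <- matrix(value, p, p, dimnames = list(names, names))
  diag(m) <- 1
  m
}

test_that("two-sample statistic has the printed standardisation", {
  p <- 3
  s1 <- fake_class_stats(make_rho(p, 0.5), make_rho(p, 0), n = 100)
  s2 <- fake_class_stats(make_rho(p, 0.2), make_rho(p, 0), n = 100)
  out <- two_sample_stat(s1, s2)
  # hand value: 0.3 / sqrt(2/100)
  expect_equal(out[1, 2], 2.12132034355964, tolerance = 1e-10)
  expect_equal(diag(out), rep(0, p), ignore_attr = TRUE)

  # identical classes give exact zeros; swapping flips every sign
  expect_equal(two_sample_stat(s1, s1), matrix(0, p, p),
               ignore_attr = TRUE)
  expect_equal(two_sample_stat(s2, s1), -out)

  # the variance plug-in uses the thresholded estimates
  s1b <- fake_class_stats(make_rho(p, 0.5), make_rho(p, 0.5), n = 100)
  out_b <- two_sample_stat(s1b, s2)
  expect_equal(out_b[1, 2],
               0.3 / sqrt((1 - 0.25)^2 / 100 + 1 / 100))

  s3 <- fake_class_stats(make_rho(4), make_rho(4), n = 50)
  expect_error(two_sample_stat(s1, s3), "different numbers")
})

test_that("multi-class combination is the entrywise sum of squares", {
  m <- function(v) matrix(v, 2, 2)
  expect_equal(multiclass_stat(list(m(1), m(2), m(-2))), m(9))
  expect_equal(multiclass_stat(list(m(0), m(0))), m(0))
  # K = 2: square of the single pairwise statistic, exactly
  x <- matrix(rnorm(9), 3)
  expect_equal(multiclass_stat(list(x)), x^2)
})

test_that("weighted chi-square CDF matches closed forms", {
  expect_equal(weighted_chisq_cdf(0, 1), 0)
  expect_equal(weighted_chisq_cdf(3.841459, 1), 0.95, tolerance = 1e-6)

  s_grid <- c(0.01, 0.5, 1, 2, 5, 10)
  # two equal unit weights: 1 - exp(-s/2)
  expect_equal(weighted_chisq_cdf(s_grid, c(1, 1)),
               1 - exp(-s_grid / 2), tolerance = 1e-10)
  # scaled single weight: P(w Z^2 <= s) = chi-square CDF at s/w
  expect_equal(weighted_chisq_cdf(2.5, 0.5), pchisq(5, 1),
               tolerance = 1e-10)

  expect_error(weighted_chisq_cdf(1, c(1, -1)), "positive")
  expect_error(weighted_chisq_cdf(-1, 1), "non-negative")
})

test_that("unequal-weight CDF agrees with Monte Carlo and is monotone", {
  w <- c(0.5, 1, 2)
  set.seed(61)
  draws <- colSums(w * matrix(rnorm(3 * 1e6)^2, 3))
  for (s in c(1, 3, 7)) {
    expect_lt(abs(weighted_chisq_cdf(s, w) - mean(draws <= s)), 1e-3)
  }
  u <- weighted_chisq_cdf(seq(0, 20, by = 0.5), w)
  expect_true(all(diff(u) >= 0))
  expect_true(all(u >= 0 & u <= 1))
})

test_that("normal-quantile transform is finite, monotone and calibrated", {
  s <- matrix(c(0.5, 0, 3.841459, 0.5), 2, 2)
  t_mat <- t_transform(s, weights = 1)
  # S = 0 clamps the CDF at 1e-15 before inversion
  expect_equal(t_mat[2, 1], qnorm(1e-15))
  expect_true(is.finite(t_mat[2, 1]))
  # chi-square 95th percentile maps to the normal 95th percentile
  expect_equal(t_mat[1, 2], qnorm(0.95), tolerance = 1e-6)
  expect_true(is.na(t_mat[1, 1]))

  s_seq <- seq(0, 30, by = 0.25)
  t_seq <- qnorm(pmin(pmax(weighted_chisq_cdf(s_seq, 1), 1e-15),
                      1 - 1e-15))
  expect_true(all(diff(t_seq) >= 0))
  expect_error(t_transform(matrix(-1, 2, 2), 1), "non-negative")
})

test_that("FDR threshold matches an exhaustive scan and handles no-signal", {
  # half the statistics large, half negative, p_tilde = 10
  t_mat <- matrix(0, 5, 5)
  vals <- c(5, 5, 5, 5, 5, -1, -1, -1, -1, -1)
  t_mat[upper.tri(t_mat)] <- vals
  t_mat <- t_mat + t(t_mat)
  out <- fdr_threshold(t_mat, 0.5)
  expect_equal(out$threshold, fdr_threshold_oracle(t_mat, 0.5))
  expect_equal(nrow(out$rejected), 5)

  # no positive statistic at all: fallback, empty rejection set
  t_low <- matrix(-10, 5, 5)
  out_low <- fdr_threshold(t_low, 0.05)
  expect_true(out_low$fallback)
  expect_equal(out_low$threshold, sqrt(4 * log(10)))
  expect_equal(nrow(out_low$rejected), 0)

  # when P0_hat equals P0 the correction constant vanishes
  expect_equal(out$constants$P0, 2 * pnorm(1) - 1)
  t_cal <- matrix(0, 5, 5)
  t_cal[upper.tri(t_cal)] <- qnorm(seq(0.05, 0.95, length.out = 10))
  n_in <- sum(abs(t_cal[upper.tri(t_cal)]) <= 1)
  out_cal <- fdr_threshold(t_cal + t(t_cal), 0.3)
  expect_equal(out_cal$constants$P0_hat, n_in / 10)

  expect_error(fdr_threshold(t_mat, 1.5), "in \\(0, 1\\)")
})

test_that("FDR threshold agrees with the scan oracle on random inputs", {
  set.seed(62)
  for (rep in 1:10) {
    p <- sample(4:10, 1)
    t_mat <- matrix(0, p, p)
    t_mat[upper.tri(t_mat)] <- rnorm(p * (p - 1) / 2, mean = 1, sd = 2)
    t_mat <- t_mat + t(t_mat)
    alpha <- runif(1, 0.05, 0.5)
    expect_equal(fdr_threshold(t_mat, alpha)$threshold,
                 fdr_threshold_oracle(t_mat, alpha))
  }
})

test_that("rejection sets grow monotonically with the FDR level", {
  set.seed(63)
  model <- band_precision(p = 20, n_flips = 5, seed = 63)
  y1 <- sample_nonparanormal(model, 80, 1, seed = 631)
  y2 <- sample_nonparanormal(model, 80, 2, seed = 632)
  res <- dnet_test(list(a = y1$observed, b = y2$observed), alpha0 = 0.05)
  prev <- character(0)
  for (a in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
    cur <- dnet_rethreshold(res, a)$rejected
    cur_keys <- paste(cur[, 1], cur[, 2])
    expect_true(all(prev %in% cur_keys))
    prev <- cur_keys
  }
})

test_that("identical classes yield no differential edges", {
  set.seed(64)
  y <- matrix(rnorm(60 * 10), 60, 10)
  res <- dnet_test(list(a = y, b = y), alpha0 = 0.05)
  expect_equal(nrow(res$rejected), 0)
  expect_true(all(res$t_stats[upper.tri(res$t_stats)] < 0))

  # structural contract of the rejection set: unordered upper-tri pairs
  model <- band_precision(p = 15, n_flips = 4, seed = 65)
  y1 <- sample_nonparanormal(model, 80, 1, seed = 651)
  y2 <- sample_nonparanormal(model, 80, 2, seed = 652)
  res2 <- dnet_test(list(a = y1$observed, b = y2$observed), alpha0 = 0.3)
  if (nrow(res2$rejected) > 0) {
    expect_true(all(res2$rejected[, 1] < res2$rejected[, 2]))
  }
})

test_that("the test is deterministic given data and configuration", {
  set.seed(66)
  model <- band_precision(p = 12, n_flips = 3, seed = 66)
  y1 <- sample_nonparanormal(model, 50, 1, seed = 661)$observed
  y2 <- sample_nonparanormal(model, 50, 2, seed = 662)$observed
  r1 <- dnet_test(list(a = y1, b = y2), alpha0 = 0.1)
  r2 <- dnet_test(list(a = y1, b = y2), alpha0 = 0.1)
  expect_identical(r1$t_stats, r2$t_stats)
  expect_identical(r1$threshold, r2$threshold)
})

test_that("three-class input combines all pairwise statistics", {
  set.seed(67)
  model <- band_precision(p = 10, n_flips = 2, seed = 67)
  y1 <- sample_nonparanormal(model, 50, 1, seed = 671)$observed
  y2 <- sample_nonparanormal(model, n = 50, class_index = 2,
                             seed = 672)$observed
  y3 <- sample_nonparanormal(model, 50, 1, seed = 673)$observed
  res <- dnet_test(list(a = y1, b = y2, c = y3), alpha0 = 0.2)
  expect_length(res$pairwise, 3)
  expect_equal(res$combined,
               res$pairwise[[1]]^2 + res$pairwise[[2]]^2 +
                 res$pairwise[[3]]^2)
  expect_length(res$weights, 3)
})
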