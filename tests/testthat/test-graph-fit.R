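test_that("adjusted-Spearman gram is a rank statistic with unit diagonal", {
  set.seed(51)
  y <- matrix(rnorm(50 * 4), 50, 4)
  g <- gram_matrix(y, "adjusted_spearman")
  expect_true(isSymmetric(g))
  expect_equal(diag(g), rep(1, 4), ignore_attr = TRUE)
  # 2 sin(pi/6) = 1 is the self-correlation identity behind the diagonal
  expect_equal(2 * sin(pi / 6), 1)

  # invariant under strictly increasing marginal transforms
  y2 <- y; y2[, 1] <- exp(y2[, 1]); y2[, 3] <- y2[, 3]^3
  expect_equal(gram_matrix(y2, "adjusted_spearman"), g,
               ignore_attr = TRUE)
  # pearson gram is not, in general
  expect_false(isTRUE(all.equal(gram_matrix(y2, "imputed"),
                                gram_matrix(y, "imputed"),
                                check.attributes = FALSE)))
})

test_that("adjusted Spearman is consistent for the latent correlation", {
  set.seed(52)
  n <- 5000
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, 0.5, 0.5, 1), 2))
  g <- gram_matrix(cbind(exp(z[, 1]), z[, 2]^3, z[, 1] + z[, 2]),
                   "adjusted_spearman")
  expect_lt(abs(g[1, 2] - 0.5), 0.05)
})

test_that("gram lasso obeys the soft-threshold kill condition and OLS limit", {
  g <- random_pd_gram(5, seed = 53)
  j <- 2
  lam_max <- max(abs(g[-j, j]))
  expect_equal(nodewise_lasso(g, j, lam_max + 1e-9),
               setNames(rep(0, 4), colnames(g)[-j]))
  ols <- solve(g[-j, -j], g[-j, j])
  expect_equal(nodewise_lasso(g, j, 0), ols, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(nodewise_lasso(matrix(c(1, 0.4, 0.1, 1), 2), 1, 0.1),
               "symmetric")
  expect_error(nodewise_lasso(g, 1, -0.5), "non-negative")
})

test_that("gram lasso matches the glmnet objective optimum", {
  for (seed in 1:5) {
    p <- 4
    g <- random_pd_gram(p, seed = 60 + seed)
    j <- 1 + (seed %% p)
    lam <- 0.1
    mine <- nodewise_lasso(g, j, lam)
    # reconstruct a data problem whose normal equations are exactly (g, j)
    m <- p - 1
    x <- sqrt(m) * chol(g[-j, -j])
    y <- drop(x %*% solve(g[-j, -j], g[-j, j]))
    fit <- glmnet::glmnet(x, y, lambda = lam, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14)
    ref <- drop(as.matrix(fit$beta))
    expect_equal(lasso_objective(g, j, mine, lam),
                 lasso_objective(g, j, ref, lam), tolerance = 1e-6)
  }
})

test_that("Dantzig selector solves the l1-minimal feasible program", {
  g <- random_pd_gram(4, seed = 54)
  j <- 1
  lam_max <- max(abs(g[-j, j]))
  expect_equal(nodewise_dantzig(g, j, lam_max + 1e-9),
               setNames(rep(0, 3), colnames(g)[-j]))
  ols <- solve(g[-j, -j], g[-j, j])
  expect_equal(nodewise_dantzig(g, j, 0), ols, tolerance = 1e-7,
               ignore_attr = TRUE)

  # vertex-enumeration oracle on the positive/negative-part LP
  lam <- 0.05
  beta <- nodewise_dantzig(g, j, lam)
  gs <- g[-j, -j]; gv <- g[-j, j]
  expect_lte(max(abs(gs %*% beta - gv)), lam + 1e-8)
  expect_equal(sum(abs(beta)), dantzig_enum_optimum(gs, gv, lam),
               tolerance = 1e-6)
  expect_lte(sum(abs(beta)), sum(abs(ols)) + 1e-8)
})

test_that("AIC path has the stated grid and endpoint behaviour", {
  set.seed(55)
  x <- rmvn_precision(120, diag(6) + 0.25, seed = 55)
  imp <- npn_impute(x)
  sel <- select_lambda_aic(imp, j = 1, n_lambdas = 20)
  expect_length(sel$grid, 20)
  expect_true(all(diff(sel$grid) < 0))
  # endpoints follow the documented rule: lambda_max down to the larger
  # of lambda_max/100 and half the universal penalty scale
  g <- gram_matrix(imp)
  lam_max <- max(abs(g[-1, 1]))
  expect_equal(sel$grid[1], lam_max)
  expect_equal(sel$grid[20],
               min(lam_max, max(lam_max / 100,
                                0.5 * sqrt(log(6) / 120))))

  # at lambda_max the fit is empty and AIC is the intercept-only value
  xs <- sweep(imp$scores, 2, colMeans(imp$scores))
  xs <- sweep(xs, 2, sqrt(colMeans(xs^2)), "/")
  rss0 <- sum((xs[, 1] - mean(xs[, 1]))^2)
  expect_equal(sel$df[1], 0)
  expect_equal(sel$aic[1], 120 * log(rss0 / 120), tolerance = 1e-10)
  expect_error(select_lambda_aic(imp, 1, n_lambdas = 1), "at least 2")
})

test_that("AIC keeps the support small under the null graph", {
  set.seed(56)
  x <- rmvn_precision(400, diag(10), seed = 56)
  imp <- npn_impute(x)
  spurious <- vapply(1:10, function(j) {
    sum(abs(select_lambda_aic(imp, j)$beta) > 1e-10)
  }, numeric(1))
  expect_lte(median(spurious), 2)
})

test_that("residual statistics reduce correctly and match hand arithmetic", {
  x <- matrix(c(2, 4, 6, 8,
                1, 3, 2, 4,
                5, 1, 4, 2), 4, 3)
  colnames(x) <- c("a", "b", "c")
  fit <- residual_stats(x, matrix(0, 3, 3))
  # with no coefficients the residuals are the centred columns
  expect_equal(fit$residuals, sweep(x, 2, colMeans(x)),
               ignore_attr = TRUE)
  # hand-computed centred cross products, 1/n convention:
  # centred a = (-3,-1,1,3), b = (-1.5,0.5,-0.5,1.5), c = (2,-2,1,-1)
  expect_equal(fit$cross_products[1, 1], 5)
  expect_equal(fit$cross_products[2, 2], 1.25)
  expect_equal(fit$cross_products[3, 3], 2.5)
  expect_equal(fit$cross_products[1, 2], (4.5 - 0.5 - 0.5 + 4.5) / 4)
  expect_equal(fit$cross_products[1, 3], (-6 + 2 + 1 - 3) / 4)
  expect_equal(fit$cross_products[2, 3], (-3 - 1 - 0.5 - 1.5) / 4)

  # fitted intercepts absorb the mean exactly
  set.seed(57)
  y <- rmvn_precision(50, diag(4) + 0.3, seed = 57)
  B <- matrix(0.1, 4, 4); diag(B) <- 0
  fit2 <- residual_stats(y, B)
  expect_lt(max(abs(colMeans(fit2$residuals))), 1e-10)

  expect_error(residual_stats(y, B[1:3, 1:3]), "p-by-p")
  expect_error(residual_stats(y, B + diag(4)), "zero diagonal")
})

test_that("bias-corrected statistic is symmetric and reduces when B = 0", {
  set.seed(58)
  y <- rmvn_precision(60, diag(4) + 0.4, seed = 58)
  fit <- residual_stats(y, matrix(0, 4, 4))
  fit$n <- nrow(y); fit$p <- 4
  stats <- bias_corrected_stat(fit)
  r <- fit$cross_products
  expected <- r / sqrt(outer(diag(r), diag(r)))
  off <- upper.tri(r)
  expect_equal(stats$rho_corrected[off], expected[off], tolerance = 1e-12)
  expect_true(all(abs(stats$rho_corrected) <= 1))
  expect_equal(stats$rho_corrected, t(stats$rho_corrected))
  expect_equal(stats$s_star[off], (r / outer(diag(r), diag(r)))[off],
               tolerance = 1e-12)
})

test_that("bias-corrected estimates recover true partial correlations", {
  omega <- matrix(c(2, 0.5, 0,
                    0.5, 1.5, 0.4,
                    0, 0.4, 1), 3, 3)
  expect_gt(min(eigen(omega, only.values = TRUE)$values), 0)
  x <- rmvn_precision(5000, omega, seed = 59)
  fit <- fit_nodewise(npn_impute(x), method = "lasso",
                      gram_source = "adjusted_spearman")
  stats <- bias_corrected_stat(fit)
  truth <- partial_cor(omega)
  off <- upper.tri(truth)
  expect_lt(max(abs(stats$rho_corrected[off] - truth[off])), 0.05)
})

test_that("hard thresholding uses the 2 sqrt(log p / n) cutoff", {
  # p = 200, n = 100: cutoff = 2 sqrt(log(200)/100) ~ 0.4604
  p <- 200; n <- 100
  rho <- matrix(0.01, p, p)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- 2 * sqrt(log(p) / n) + 1e-6
  diag(rho) <- 1
  out <- threshold_partial_corr(rho, n = n)
  expect_equal(out[1, 2], 0.9)
  expect_gt(abs(out[3, 4]), 0)
  expect_equal(out[5, 6], 0)
  expect_equal(sum(out != 0), 4 + p)  # two surviving pairs plus diagonal

  # idempotent projection
  expect_equal(threshold_partial_corr(out, n = n), out)
})
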