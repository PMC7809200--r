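test_that("orthogonal polynomial basis is orthonormal and matches Gram-Schmidt", {
  b <- build_orthopoly(c(10, 20, 30), 2)
  expect_equal(abs(b$columns[, 1]), abs(c(-1, 0, 1) / sqrt(2)), tolerance = 1e-10)
  expect_equal(abs(b$columns[, 2]), abs(c(1, -2, 1) / sqrt(6)), tolerance = 1e-10)

  set.seed(31)
  for (i in 1:5) {
    ages <- runif(50, 10, 86)
    b <- build_orthopoly(ages, 3)
    G <- crossprod(b$columns)
    expect_true(max(abs(G - diag(3))) < 1e-10)
    expect_true(max(abs(colSums(b$columns))) < 1e-10)
    # independent oracle: Gram-Schmidt on (age, age^2, age^3), up to sign
    Q <- gram_schmidt_poly(ages, 3)
    for (j in 1:3) {
      expect_lt(min(max(abs(b$columns[, j] - Q[, j])),
                    max(abs(b$columns[, j] + Q[, j]))), 1e-8)
    }
  }
  # evaluation at the anchor ages reproduces the columns
  ages <- runif(30, 10, 86)
  b <- build_orthopoly(ages, 3)
  expect_equal(eval_orthopoly(b, ages), b$columns, tolerance = 1e-12)
  expect_error(build_orthopoly(c(10, 10, 20), 2), "distinct ages")
})

test_that("trajectory fits agree with the normal-equations oracle", {
  set.seed(17)
  n <- 40
  ages <- runif(n, 10, 86)
  cov_m <- cbind(iq = rnorm(n, 110, 12), ses = sample(3:20, n, TRUE))
  y <- 50 - 0.2 * ages + 0.1 * cov_m[, 1] + rnorm(n, 0, 3)
  fit <- fit_trajectory(y, ages, cov_m, degree = 2)
  X <- cbind(1, build_orthopoly(ages, 2)$columns, cov_m)
  b_oracle <- ols_normal_equations(X, y)
  expect_equal(unname(fit$coefficients), unname(b_oracle), tolerance = 1e-8)
  expect_equal(fit$rss, sum((y - X %*% b_oracle)^2), tolerance = 1e-8)
  # standardized betas equal the refit on z-scored columns
  Xz <- scale(X[, -1]); yz <- scale(y)[, 1]
  bz <- ols_normal_equations(cbind(1, Xz), yz)[-1]
  expect_equal(unname(fit$beta_std), unname(bz), tolerance = 1e-8)
})

test_that("an exactly linear outcome fits perfectly with null higher terms", {
  ages <- seq(10, 86, length.out = 60)
  y <- 3 + 0.5 * ages
  fit <- fit_trajectory(y, ages, NULL, degree = 3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients[c("age2", "age3")])), 1e-8)
})

test_that("degrees of freedom and information criteria follow the stated conventions", {
  set.seed(23)
  n <- 340
  ages <- runif(n, 10, 86)
  cov_m <- cbind(iq = rnorm(n, 110, 12), ses = rnorm(n, 14, 4))
  y <- 0.02 * ages - 2e-4 * (ages - 45)^2 + 0.01 * cov_m[, 1] + rnorm(n)
  fit2 <- fit_trajectory(y, ages, cov_m, degree = 2)
  # a quadratic model with two covariates on 340 rows: F(4, 335)
  expect_equal(fit2$f_overall$df1, 4)
  expect_equal(fit2$f_overall$df2, 335)
  for (d in 1:3) {
    fit <- fit_trajectory(y, ages, cov_m, degree = d)
    # aic = 2k - 2LL and bic = k ln(n) - 2LL imply bic - aic = k (ln n - 2)
    expect_equal(fit$aic, 2 * fit$k_params - 2 * fit$loglik)
    expect_equal(fit$bic, fit$k_params * log(n) - 2 * fit$loglik)
    expect_equal(fit$bic - fit$aic, fit$k_params * (log(n) - 2))
    # log-likelihood matches the closed Gaussian profile form
    expect_equal(fit$loglik, -n / 2 * (log(2 * pi) + log(fit$rss / n) + 1))
  }
  # the linear model with two covariates has k = 5 parameters, so on
  # n = 340 its bic - aic gap is 5 (ln 340 - 2) = 19.14
  fit1 <- fit_trajectory(y, ages, cov_m, degree = 1)
  expect_equal(fit1$k_params, 5)
  expect_equal(round(fit1$bic - fit1$aic, 2), 19.14)
  # RSS never increases with degree
  rss <- vapply(1:3, function(d) fit_trajectory(y, ages, cov_m, d)$rss, 0)
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("nested comparison reproduces F-change, LR and information deltas", {
  set.seed(29)
  n <- 200
  ages <- runif(n, 10, 86)
  y <- 0.03 * ages + rnorm(n)
  f1 <- fit_trajectory(y, ages, NULL, 1)
  f2 <- fit_trajectory(y, ages, NULL, 2)
  cmp <- compare_nested(f1, f2)
  expect_equal(cmp$lr_chisq$statistic, 2 * (f2$loglik - f1$loglik))
  expect_gte(cmp$lr_chisq$statistic, 0)
  expect_equal(cmp$f_change$df1, f2$k_coef - f1$k_coef)
  expect_equal(cmp$delta_aic, f2$aic - f1$aic)
  expect_equal(cmp$delta_bic, f2$bic - f1$bic)
  # cross-check the F-change against stats::anova on equivalent lm fits
  P <- build_orthopoly(ages, 2)$columns
  a <- anova(lm(y ~ P[, 1]), lm(y ~ P))
  expect_equal(cmp$f_change$statistic, a$F[2], tolerance = 1e-8)
  expect_equal(cmp$f_change$p, a$`Pr(>F)`[2], tolerance = 1e-8)

  # a higher-degree term that adds exactly nothing gives F = 0, chisq = 0, p = 1
  P3 <- build_orthopoly(ages, 3)$columns
  e <- qr.resid(qr(cbind(1, P3)), rnorm(n))   # noise orthogonal to all terms
  y0 <- 5 + 2 * P3[, 1] + e
  g1 <- fit_trajectory(y0, ages, NULL, 1)
  g2 <- fit_trajectory(y0, ages, NULL, 2)
  cmp0 <- compare_nested(g1, g2)
  expect_equal(cmp0$f_change$statistic, 0, tolerance = 1e-8)
  expect_equal(cmp0$lr_chisq$statistic, 0, tolerance = 1e-6)
  expect_equal(cmp0$f_change$p, 1, tolerance = 1e-6)

  expect_error(compare_nested(f2, f1), "higher polynomial degree")
})

test_that("the change-F p-value is uniform under a true linear model", {
  set.seed(37)
  nrep <- 500
  ages <- runif(120, 10, 86)
  pvals <- vapply(seq_len(nrep), function(i) {
    y <- 1 + 0.05 * ages + rnorm(120)
    compare_nested(fit_trajectory(y, ages, NULL, 1),
                   fit_trajectory(y, ages, NULL, 2))$f_change$p
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("model selection follows the hierarchical four-index majority vote", {
  set.seed(43)
  n <- 350
  ages <- runif(n, 10, 86)
  P <- build_orthopoly(ages, 3)$columns

  # strong quadratic signal: degree 2 wins 1v2, and the cubic adds nothing
  y2 <- 10 + 3 * P[, 1] + 4 * P[, 2] + rnorm(n, 0, 0.8)
  sel2 <- select_best_model(y2, ages)
  expect_equal(sel2$chosen_degree, 2)
  expect_true(all(sel2$votes[["1v2"]]))

  # pure linear signal stays linear
  y1 <- 2 + 5 * P[, 1] + rnorm(n, 0, 1)
  sel1 <- select_best_model(y1, ages)
  expect_equal(sel1$chosen_degree, 1)

  # an AIC-only improvement is a 1-of-4 minority: the simpler model is kept.
  # Engineer a cubic component whose chi-square gain sits between 2 and 3.84
  # (AIC favours the cubic, both p-values and BIC favour the quadratic).
  e <- qr.resid(qr(cbind(1, P)), rnorm(n))
  e <- e / sd(e)
  for (amp in seq(1.4, 1.9, by = 0.05)) {
    y <- 10 + 3 * P[, 1] + 4 * P[, 2] + amp * P[, 3] + e
    f2 <- fit_trajectory(y, ages, NULL, 2)
    f3 <- fit_trajectory(y, ages, NULL, 3)
    cmp <- compare_nested(f2, f3)
    if (cmp$delta_aic < 0 && cmp$f_change$p >= 0.05 && cmp$delta_bic > 0) {
      sel <- select_best_model(y, ages)
      expect_equal(sel$chosen_degree, 2)
      expect_equal(sum(sel$votes[["2v3"]]), 1L)
      break
    }
  }

  # covariate-free refits use the same machinery with fewer columns
  expect_equal(sel2$fits[[2]]$k_coef, 3)
  sel2c <- select_best_model(y2, ages, cbind(iq = rnorm(n), ses = rnorm(n)))
  expect_equal(sel2c$fits[[2]]$k_coef, 5)
  expect_equal(sel2c$chosen_degree, 2)
})

test_that("residualize matches the hat-matrix oracle and its orthogonality contract", {
  set.seed(53)
  n <- 20
  X <- cbind(rnorm(n), runif(n))
  y <- 2 + X %*% c(1, -2) + rnorm(n)
  r <- residualize(drop(y), X)
  expect_equal(r, hat_matrix_residuals(cbind(1, X), drop(y)), tolerance = 1e-10)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(max(abs(crossprod(X, r))), 1e-8)

  # outcome identical to a predictor -> all-zero residuals
  expect_lt(max(abs(residualize(X[, 1], X))), 1e-10)
  # outcome orthogonal to centered predictors -> centered outcome returned
  yo <- qr.resid(qr(cbind(1, X)), rnorm(n))
  expect_equal(residualize(yo + 5, X), yo, tolerance = 1e-10)
  expect_error(residualize(drop(y), cbind(X, X[, 1])), "rank deficient")
})

test_that("predicted curves are consistent in-sample and recover a known peak", {
  ages <- seq(10, 86, length.out = 80)
  y <- 4 - 0.001 * (ages - 30)^2
  fit <- fit_trajectory(y, ages, NULL, 2)
  expect_equal(predict_curve(fit, ages), fit$fitted, tolerance = 1e-8)

  yc <- rep(3.3, 80)
  fitc <- fit_trajectory(yc + rnorm(80, 0, 1e-8), ages, NULL, 1)
  expect_equal(predict_curve(fitc, c(20, 50, 80)), rep(3.3, 3), tolerance = 1e-4)

  expect_warning(predict_curve(fit, 95), "extrapolation")

  # peak recovery within +/- 3 years across 100 noisy replicates
  set.seed(59)
  peaks <- vapply(1:100, function(i) {
    a <- runif(350, 10, 86)
    yy <- 4 - 0.0012 * (a - 30)^2 + rnorm(350, 0, 0.4)
    f <- fit_trajectory(yy, a, NULL, 2)
    grid <- seq(min(a), max(a), length.out = 600)
    grid[which.max(predict_curve(f, grid))]
  }, 0)
  expect_true(all(abs(peaks - 30) <= 3))
})
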