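test_that("icc_two_way matches the ANOVA mean-squares oracle", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- icc_two_way(a, b)
  expect_equal(res$estimate, icc21_aov_oracle(a, b), tolerance = 1e-10)
  expect_lt(res$estimate, 0.2)   # absolute agreement penalizes the offset
  set.seed(41)
  for (rep in 1:5) {
    x <- rnorm(12, 50, 5); y <- x + rnorm(12, 0, 2)
    expect_equal(icc_two_way(x, y)$estimate, icc21_aov_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("icc_two_way handles identity, consistency and degeneracies", {
  x <- c(4, 8, 15, 16, 23, 42)
  res <- icc_two_way(x, x)
  expect_equal(res$estimate, 1)
  expect_equal(res$band, "excellent")
  expect_equal(res$n_pairs, 6)
  # consistency variant ignores a constant offset entirely
  cons <- icc_two_way(x, x + 10, type = "consistency")
  expect_equal(cons$estimate, 1, tolerance = 1e-12)
  expect_error(icc_two_way(c(1, 2), c(1, 2)),
               class = "fp_error_sample_size")
  expect_warning(und <- icc_two_way(rep(5, 4), rep(5, 4)), "undefined")
  expect_true(is.na(und$estimate))
})

test_that("ICC estimates recover their simulated truth across bands", {
  # 200 tables per theoretical ICC at n = 50: mean estimate within 0.05
  for (rho in c(0.5, 0.75, 0.9, 0.95)) {
    sig_e <- 1
    sig_b <- rho / (1 - rho) * sig_e
    ests <- vapply(1:200, function(r) {
      tab <- simulate_paired_measurements(50, sig_b, sig_e, sig_e,
                                          seed = 1000 * rho + r)
      icc_two_way(tab$method_a, tab$method_b)$estimate
    }, numeric(1))
    expect_lt(abs(mean(ests) - rho), 0.05)
  }
})

test_that("classify_icc applies the published bands and boundaries", {
  expect_equal(classify_icc(0.97), "excellent")
  expect_equal(classify_icc(0.3), "poor")
  expect_equal(classify_icc(0.8), "good")
  expect_equal(classify_icc(0.5), "moderate")
  expect_equal(classify_icc(0.75), "moderate")
  expect_equal(classify_icc(0.9), "good")
  expect_equal(classify_icc(0.9000001), "excellent")
  expect_error(classify_icc(NaN), class = "fp_error_value")
})

test_that("fit_multiple_regression agrees with the normal-equation oracle", {
  set.seed(43)
  X <- data.frame(thickness = rnorm(12, 0.6, 0.1),
                  head_area = rnorm(12, 150, 30),
                  notch_area = rnorm(12, 60, 10))
  y <- 5 + 2 * X$thickness + 0.1 * X$head_area - 0.05 * X$notch_area +
    rnorm(12, 0, 0.5)
  fit <- fit_multiple_regression(y, X)
  oracle <- ols_oracle(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)
  expect_lte(fit$adjusted_r_squared, fit$r_squared)
  expect_equal(fit$cohens_f2, fit$r_squared / (1 - fit$r_squared))
  # VIFs equal the auxiliary-regression definition
  for (j in seq_along(X)) {
    aux <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    expect_equal(unname(fit$vifs[j]), 1 / (1 - aux), tolerance = 1e-8)
  }
})

test_that("regression edge cases behave as specified", {
  set.seed(44)
  x <- rnorm(10)
  fit <- suppressWarnings(fit_multiple_regression(x, data.frame(x = x)))
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients["x"]), 1)
  # orthogonal centered predictors have VIF exactly 1
  X <- data.frame(a = rep(c(-1, 1), 6), b = rep(c(-1, -1, 1, 1), 3),
                  c = rnorm(12))
  X$c <- stats::residuals(lm(c ~ a + b, data = X))  # orthogonalize
  y <- rnorm(12)
  fit2 <- fit_multiple_regression(y, X)
  expect_equal(unname(fit2$vifs[1:2]), c(1, 1), tolerance = 1e-10)
  # rank deficiency names the aliased column
  X$dup <- X$a
  expect_error(fit_multiple_regression(y, X),
               class = "fp_error_collinearity")
  expect_error(fit_multiple_regression(y, X), "dup")
  expect_error(fit_multiple_regression(rnorm(4),
                                       data.frame(a = rnorm(4),
                                                  b = rnorm(4),
                                                  c = rnorm(4))),
               class = "fp_error_sample_size")
})

test_that("standardized betas come from z-scored variables", {
  set.seed(45)
  X <- data.frame(a = rnorm(20, 10, 3), b = rnorm(20, -5, 7))
  y <- 1 + 0.5 * X$a - 0.2 * X$b + rnorm(20)
  fit <- fit_multiple_regression(y, X)
  zo <- ols_oracle(scale(X), as.vector(scale(y)))
  expect_equal(unname(fit$standardized_betas), unname(zo[-1]),
               tolerance = 1e-8)
})

test_that("cohens_f2 follows its defining formula", {
  expect_equal(cohens_f2(0), 0)
  expect_equal(cohens_f2(0.5), 1)
  expect_error(cohens_f2(1), class = "fp_error_value")
  expect_error(cohens_f2(-0.1), class = "fp_error_value")
})

test_that("posthoc_power matches a numeric noncentral-F oracle", {
  pr <- posthoc_power(f2 = 0.35, n = 40, k = 5, alpha = 0.05)
  expect_equal(pr$noncentrality, 0.35 * 40)
  expect_equal(pr$power,
               ncf_tail_oracle(pr$critical_f, 5, 34, 0.35 * 40),
               tolerance = 1e-8)
  # the central case collapses to the significance level
  expect_equal(posthoc_power(0, 20, 3, 0.05)$power, 0.05, tolerance = 1e-10)
  # monotone in f2, n and alpha
  p_n <- vapply(c(11, 20, 30), function(n)
    posthoc_power(2.62, n, 6, 0.05)$power, numeric(1))
  expect_true(all(diff(p_n) > 0))
  p_f <- vapply(c(0.1, 0.5, 1, 2.62), function(f)
    posthoc_power(f, 11, 6, 0.05)$power, numeric(1))
  expect_true(all(diff(p_f) > 0))
  p_a <- vapply(c(0.01, 0.05, 0.1), function(a)
    posthoc_power(2.62, 11, 6, a)$power, numeric(1))
  expect_true(all(diff(p_a) > 0))
  expect_error(posthoc_power(1, 5, 6), class = "fp_error_value")
})

test_that("mean_sd uses the sample (n-1) standard deviation", {
  expect_equal(mean_sd(c(1, 1, 1)), c(mean = 1, sd = 0))
  expect_equal(mean_sd(c(1, 2, 3)), c(mean = 2, sd = 1))
  x <- c(2.5, 7.1, 4.4, 9)
  shifted <- mean_sd(x + 100)
  expect_equal(unname(shifted["mean"]), mean(x) + 100)
  expect_equal(unname(shifted["sd"]), unname(mean_sd(x)["sd"]))
  expect_error(mean_sd(1), class = "fp_error_sample_size")
})
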