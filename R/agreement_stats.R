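#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' Computes the single-measure ICC between two measurement methods from
#' the two-way ANOVA mean squares (rows = specimens, columns = methods).
#' The default formulation is ICC(2,1): two-way random effects, absolute
#' agreement, single measurement,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`;
#' the consistency variant `(MSR - MSE) / (MSR + (k-1) MSE)` is available
#' behind `type = "consistency"`. The estimate is banded as poor
#' (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or excellent (> 0.9).
#'
#' @param pairs Two-column numeric matrix/data.frame of per-specimen
#'   values, or the first method's vector when `b` is given.
#' @param b Optional second method's vector.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return Object of class `icc_result` with fields `estimate`,
#'   `model_tag`, `band`, `n_pairs` and the mean squares.
#' @export
#' @examples
#' tab <- simulate_paired_measurements(30, 9, 1, 1, seed = 2)
#' icc_two_way(tab$method_a, tab$method_b)
icc_two_way <- function(pairs, b = NULL,
                        type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (!is.null(b)) pairs <- cbind(pairs, b)
  if (is.data.frame(pairs)) {
    num <- vapply(pairs, is.numeric, logical(1))
    pairs <- as.matrix(pairs[, num, drop = FALSE])
  }
  m <- as.matrix(pairs)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) != 2L)
    stop_fp("exactly two measurement columns are required",
            "fp_error_value")
  n <- nrow(m); k <- 2L
  if (n < 3)
    stop_fp("at least 3 complete pairs are required",
            "fp_error_sample_size")
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- if (type == "agreement")
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  else msr + (k - 1) * mse
  if (sst < .Machine$double.eps * max(1, abs(grand))^2 || denom <= 0) {
    warning("total variance is zero; ICC undefined")
    est <- NA_real_
  } else {
    est <- (msr - mse) / denom
  }
  structure(list(estimate = est,
                 model_tag = if (type == "agreement")
                   "ICC(2,1) two-way random, absolute agreement, single"
                 else "ICC(3,1)-style consistency, single",
                 band = if (is.na(est)) NA_character_ else classify_icc(est),
                 n_pairs = n,
                 mean_squares = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f (%s), n = %d pairs\n  model: %s\n",
              x$estimate, x$band, x$n_pairs, x$model_tag))
  invisible(x)
}

#' Agreement band of an ICC estimate
#'
#' Bands: poor (< 0.5), moderate (0.5 to 0.75), good (above 0.75 up to
#' 0.9) and excellent (> 0.9). Boundary values fall in the lower-named
#' band, so 0.5 and 0.75 are moderate and 0.9 is good.
#'
#' @param estimate Finite ICC estimate.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
#' @examples
#' classify_icc(0.97)  # excellent
classify_icc <- function(estimate) {
  if (!is.numeric(estimate) || length(estimate) != 1L ||
      !is.finite(estimate))
    stop_fp("estimate must be a single finite number", "fp_error_value")
  if (estimate < 0.5) "poor"
  else if (estimate <= 0.75) "moderate"
  else if (estimate <= 0.9) "good"
  else "excellent"
}

#' Multiple linear regression with agreement-study diagnostics
#'
#' Ordinary least squares of a response on named predictors with the usual
#' model-fit diagnostics: R-squared, adjusted R-squared, overall F and its
#' p-value, per-coefficient tests, standardized betas (from z-scored
#' variables), variance inflation factors, Cohen's f-squared, and residual
#' versus theoretical normal quantiles for Q-Q inspection.
#'
#' @param response Numeric vector.
#' @param predictors Numeric matrix or data.frame with column names.
#' @return Object of class `regression_result`.
#' @export
fit_multiple_regression <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    stop_fp("predictors must be named", "fp_error_value")
  y <- as.numeric(response)
  n <- length(y)
  k <- ncol(predictors)
  if (n != nrow(predictors))
    stop_fp("response and predictors differ in length", "fp_error_value")
  if (n <= k + 1)
    stop_fp("need more observations than predictors plus intercept",
            "fp_error_sample_size")
  dat <- cbind(.response = y, predictors)
  fit <- lm(.response ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_fp(paste0("predictors are rank deficient; aliased: ",
                   paste(bad, collapse = ", ")), "fp_error_collinearity")
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  zdat <- as.data.frame(scale(dat))
  zfit <- lm(.response ~ ., data = zdat)
  vifs <- if (k >= 2) car::vif(fit) else stats::setNames(1, names(predictors))
  fstat <- sm$fstatistic
  res <- stats::residuals(fit)
  structure(list(
    coefficients = coef(fit),
    standardized_betas = coef(zfit)[-1],
    r_squared = r2,
    adjusted_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat[1]),
    model_p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE)),
    p_values = sm$coefficients[, 4],
    vifs = vifs,
    cohens_f2 = if (r2 < 1) cohens_f2(r2) else Inf,
    n = n, k = k,
    residuals = res,
    theoretical_quantiles = qnorm(ppoints(n))[order(order(res))]),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(paste0("regression_result: n = %d, k = %d\n",
                     "  R^2 = %.3f (adjusted %.3f), F = %.3f, p = %.3f, ",
                     "f^2 = %.2f\n"),
              x$n, x$k, x$r_squared, x$adjusted_r_squared, x$f_statistic,
              x$model_p_value, x$cohens_f2))
  tab <- data.frame(beta = x$standardized_betas,
                    p = x$p_values[-1],
                    VIF = unname(x$vifs))
  print(round(tab, 3))
  invisible(x)
}

#' Cohen's f-squared from R-squared
#'
#' `f^2 = R^2 / (1 - R^2)`, the effect size of an R-squared-deviation-
#' from-zero F test.
#'
#' @param r_squared Value in \[0, 1).
#' @return Non-negative scalar.
#' @export
#' @examples
#' cohens_f2(0.724)  # ~2.62
cohens_f2 <- function(r_squared) {
  if (!is.numeric(r_squared) || length(r_squared) != 1L ||
      !is.finite(r_squared) || r_squared < 0 || r_squared >= 1)
    stop_fp("r_squared must lie in [0, 1)", "fp_error_value")
  r_squared / (1 - r_squared)
}

#' Post hoc power of an R-squared-deviation-from-zero F test
#'
#' Fixed-model power at effect size `f2` with `n` observations and `k`
#' predictors: noncentrality `lambda = f2 * n`, critical value the upper-
#' `alpha` quantile of the central F with (k, n - k - 1) degrees of
#' freedom, and power the upper tail of the noncentral F there.
#'
#' @param f2 Cohen's f-squared, >= 0.
#' @param n Sample size (> k + 1).
#' @param k Number of predictors (>= 1).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return Object of class `power_result`.
#' @export
#' @examples
#' posthoc_power(f2 = 2.62, n = 11, k = 6, alpha = 0.05)
posthoc_power <- function(f2, n, k, alpha = 0.05) {
  if (f2 < 0) stop_fp("f2 must be >= 0", "fp_error_value")
  if (alpha <= 0 || alpha >= 1)
    stop_fp("alpha must lie in (0, 1)", "fp_error_value")
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1 || n <= k + 1)
    stop_fp("degrees of freedom require n > k + 1 and k >= 1",
            "fp_error_value")
  df1 <- k
  df2 <- n - k - 1L
  lambda <- f2 * n
  crit <- qf(1 - alpha, df1, df2)
  power <- pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  structure(list(power = power, alpha = alpha, f2 = f2, n = n, k = k,
                 noncentrality = lambda, critical_f = crit,
                 df1 = df1, df2 = df2),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("power_result: power = %.3f at alpha = %.3f\n",
                     "  f^2 = %.3f, n = %d, k = %d, lambda = %.2f, ",
                     "critical F(%d, %d) = %.3f\n"),
              x$power, x$alpha, x$f2, x$n, x$k, x$noncentrality,
              x$df1, x$df2, x$critical_f))
  invisible(x)
}

#' Mean and sample standard deviation
#'
#' @param values Numeric vector with at least 2 values.
#' @return Named numeric vector `c(mean, sd)` (n - 1 denominator).
#' @export
mean_sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop_fp("need at least 2 values", "fp_error_sample_size")
  c(mean = mean(values), sd = sd(values))
}
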