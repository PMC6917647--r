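test_that("normal MLE closed form: n denominator, exact on {1,2,3}", {
  fit <- fit_normal_mle(c(1, 2, 3))
  expect_equal(fit$mu_hat, 2)
  expect_equal(fit$sigma2_hat, 2 / 3)
  expect_equal(fit$sigma_hat, sqrt(2 / 3))
  expect_equal(fit$n, 3)
})

test_that("degenerate and undersized inputs error", {
  expect_error(fit_normal_mle(c(5, 5, 5)), "degenerate")
  expect_error(fit_normal_mle(7), "at least 2")
  expect_error(fit_normal_mle(c(1, NA)), "finite")
})

test_that("MLE matches an independent two-pass summation oracle", {
  set.seed(11)
  x <- rnorm(500, 10, 2)
  fit <- fit_normal_mle(x)
  # oracle: explicit two-pass sums
  n <- length(x)
  mu_o <- sum(x) / n
  s2_o <- sum((x - mu_o)^2) / n
  expect_equal(fit$mu_hat, mu_o, tolerance = 1e-12)
  expect_equal(fit$sigma2_hat, s2_o, tolerance = 1e-12)
  # log-likelihood equals the summed per-point normal log-density
  expect_equal(fit$log_likelihood,
               sum(dnorm(x, mu_o, sqrt(s2_o), log = TRUE)),
               tolerance = 1e-9)
})

test_that("fit is location-scale equivariant", {
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(50, runif(1, -5, 5), runif(1, 0.5, 3))
    a <- runif(1, -2, 2); if (abs(a) < 0.1) a <- 0.5
    b <- runif(1, -10, 10)
    f0 <- fit_normal_mle(x)
    f1 <- fit_normal_mle(a * x + b)
    expect_equal(f1$mu_hat, a * f0$mu_hat + b, tolerance = 1e-10)
    expect_equal(f1$sigma_hat, abs(a) * f0$sigma_hat, tolerance = 1e-10)
  }
})

test_that("log-likelihood is maximal at the MLE on a perturbation grid", {
  set.seed(8)
  x <- rnorm(100, 4, 1.5)
  fit <- fit_normal_mle(x)
  ll <- function(mu, s2) sum(dnorm(x, mu, sqrt(s2), log = TRUE))
  for (d in c(-0.5, -0.1, 0.1, 0.5)) {
    expect_lt(ll(fit$mu_hat + d, fit$sigma2_hat), fit$log_likelihood)
    expect_lt(ll(fit$mu_hat, fit$sigma2_hat * (1 + d)), fit$log_likelihood)
  }
})

test_that("parameter recovery at the control-cohort size (n = 36)", {
  set.seed(2024)
  true_mu <- 100; true_sd <- 15; n <- 36
  fits <- replicate(200, {
    f <- fit_normal_mle(rnorm(n, true_mu, true_sd))
    c(f$mu_hat, f$sigma2_hat)
  })
  expect_equal(mean(fits[1, ]), true_mu, tolerance = 0.01)
  # n-denominator variance is biased by (n-1)/n
  expect_equal(mean(fits[2, ]), true_sd^2 * (n - 1) / n, tolerance = 0.1)
})

test_that("moment diagnostics recover theoretical skewness/kurtosis", {
  set.seed(99)
  d_norm <- moments_diagnostics(rnorm(10000), n_boot = 0)
  expect_lt(abs(d_norm$skewness), 0.1)
  expect_lt(abs(d_norm$kurtosis - 3), 0.2)

  d_exp <- moments_diagnostics(rexp(10000), n_boot = 0)
  expect_lt(abs(d_exp$skewness - 2), 0.3)
  expect_lt(abs(d_exp$kurtosis - 9), 2)
})

test_that("bootstrap is seeded, bit-identical, and moment-feasible", {
  set.seed(4)
  x <- rgamma(60, 3, 1)
  d1 <- moments_diagnostics(x, n_boot = 50, seed = 17)
  d2 <- moments_diagnostics(x, n_boot = 50, seed = 17)
  expect_identical(d1$bootstrap, d2$bootstrap)
  expect_equal(nrow(d1$bootstrap), 50)
  # kurtosis >= 1 + skewness^2 for every resample
  expect_true(all(d1$bootstrap$kurtosis >=
                    1 + d1$bootstrap$skewness^2 - 1e-9))
  expect_error(moments_diagnostics(c(1, 2, 3)), "at least 4")
})

test_that("moment estimators agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  x <- rlnorm(500)
  d <- moments_diagnostics(x, n_boot = 0)
  expect_equal(d$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
})

test_that("candidate-family ranking identifies the generating family", {
  set.seed(21)
  fits_n <- fit_candidates(rnorm(1000, 50, 5))
  expect_equal(fits_n$family[1], "normal")

  set.seed(22)
  fits_ln <- fit_candidates(rlnorm(1000, 1, 0.9))
  expect_lt(which(fits_ln$family == "lognormal"),
            which(fits_ln$family == "normal"))
})

test_that("support violations flag families instead of fitting them", {
  set.seed(23)
  x <- c(rnorm(100, 5, 1), -1)
  fits <- fit_candidates(x)
  bad <- fits$family %in% c("exponential", "lognormal", "gamma")
  expect_false(any(fits$fit_ok[bad]))
  expect_true(all(fits$fit_ok[fits$family %in% c("normal", "uniform",
                                                 "logistic", "beta")]))
  # AIC consistency: aic = 2k - 2 lnL for the fitted rows
  k <- c(normal = 2, uniform = 2, exponential = 1, logistic = 2, beta = 2,
         lognormal = 2, gamma = 2)
  ok <- fits$fit_ok
  expect_equal(fits$aic[ok],
               2 * unname(k[fits$family[ok]]) - 2 * fits$log_likelihood[ok])
  # ranked ascending by AIC among fitted families
  expect_false(is.unsorted(fits$aic[ok]))
})

test_that("all seven families are attempted", {
  set.seed(25)
  fits <- fit_candidates(rgamma(500, 4, 2))
  expect_setequal(fits$family,
                  c("normal", "uniform", "exponential", "logistic", "beta",
                    "lognormal", "gamma"))
})

test_that("qq_points: diagonal by construction, sorted, order-invariant", {
  fit <- fit_normal_mle(c(0, 1, 2, 3, 4))
  # values placed exactly at the fitted quantiles
  n <- 20
  p <- (seq_len(n) - 0.5) / n
  vals <- qnorm(p, fit$mu_hat, fit$sigma_hat)
  qq <- qq_points(vals, fit)
  expect_equal(max(abs(qq$theoretical - qq$empirical)), 0, tolerance = 1e-12)

  set.seed(31)
  x <- rnorm(1000, 7, 2)
  f <- fit_normal_mle(x)
  qq2 <- qq_points(x, f)
  expect_false(is.unsorted(qq2$theoretical))
  expect_false(is.unsorted(qq2$empirical))
  # order statistics hug the diagonal for a matching fit
  expect_lt(max(abs(qq2$theoretical - qq2$empirical)),
            4 * f$sigma_hat / sqrt(1000) * 10)
  expect_equal(qq_points(rev(x), f), qq2)
})
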