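#' Maximum-likelihood normal fit to control normalized counts
#'
#' Fits a normal distribution by maximum likelihood using the closed-form
#' estimators with the n denominator:
#' \deqn{\hat\mu = \sum_i x_i / n, \qquad
#'       \hat\sigma^2 = \sum_i (x_i - \hat\mu)^2 / n,}
#' and records the log-likelihood at the optimum,
#' \deqn{\ln L = -\frac{n}{2}\ln(2\pi) - \frac{n}{2}\ln\hat\sigma^2
#'       - \frac{1}{2\hat\sigma^2}\sum_i (x_i - \hat\mu)^2.}
#' Note the maximum-likelihood variance divides by n, not n - 1; the
#' downstream Z-scores use \eqn{\hat\sigma = \sqrt{\hat\sigma^2}}.
#'
#' @param values numeric vector of control normalized counts, length >= 2.
#' @return A list of class `normal_fit` with elements `mu_hat`,
#'   `sigma2_hat`, `sigma_hat`, `n`, `log_likelihood`.
#' @export
#' @examples
#' fit_normal_mle(c(1, 2, 3)) # mu_hat 2, sigma2_hat 2/3
fit_normal_mle <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and non-missing", call. = FALSE)
  }
  n <- length(values)
  if (n < 2) stop("need at least 2 values to fit", call. = FALSE)
  mu <- sum(values) / n
  ss <- sum((values - mu)^2)
  sigma2 <- ss / n
  if (sigma2 == 0) {
    stop("degenerate fit: all control values identical", call. = FALSE)
  }
  ll <- -(n / 2) * log(2 * pi) - (n / 2) * log(sigma2) - ss / (2 * sigma2)
  structure(list(mu_hat = mu, sigma2_hat = sigma2, sigma_hat = sqrt(sigma2),
                 n = n, log_likelihood = ll),
            class = "normal_fit")
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf("normal fit (MLE, n = %d): mu = %.4g, sigma = %.4g, lnL = %.4g\n",
              x$n, x$mu_hat, x$sigma_hat, x$log_likelihood))
  invisible(x)
}

#' Skewness-kurtosis diagnostics (Cullen-Frey plane)
#'
#' Sample skewness and kurtosis by moment estimators, plus seeded bootstrap
#' resamples, for locating the control distribution on the
#' skewness-kurtosis plane relative to the parametric families. Kurtosis is
#' on the Pearson scale (normal = 3).
#'
#' @param values numeric vector, length >= 4.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer RNG seed for the bootstrap.
#' @return A list of class `moments_diag`: `skewness`, `kurtosis`,
#'   `bootstrap` (data.frame of resampled skewness/kurtosis pairs),
#'   `n_boot`, `seed`.
#' @export
moments_diagnostics <- function(values, n_boot = 100, seed = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("need at least 4 values for kurtosis", call. = FALSE)
  sk <- function(x) {
    m <- mean(x)
    m2 <- mean((x - m)^2)
    c(skewness = mean((x - m)^3) / m2^1.5,
      kurtosis = mean((x - m)^4) / m2^2)
  }
  obs <- sk(values)
  boot <- if (n_boot > 0) {
    withr::with_seed(seed, {
      t(vapply(seq_len(n_boot),
               function(i) sk(sample(values, n, replace = TRUE)),
               c(skewness = 0, kurtosis = 0)))
    })
  } else {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("skewness", "kurtosis")))
  }
  structure(list(skewness = unname(obs["skewness"]),
                 kurtosis = unname(obs["kurtosis"]),
                 bootstrap = as.data.frame(boot),
                 n_boot = n_boot, seed = seed),
            class = "moments_diag")
}

#' Fit candidate parametric families and rank by AIC
#'
#' Fits each of seven families (normal, uniform, exponential, logistic,
#' beta, lognormal, gamma) to the data by maximum likelihood on its valid
#' support and ranks them by ascending AIC. Families whose support the data
#' violate (negative values for exponential/lognormal/gamma, non-positive
#' for lognormal/gamma) are flagged `fit_ok = FALSE` and sorted last. The
#' beta family is fitted after an affine rescale of the data into (0, 1)
#' with a 0.5% margin; its log-likelihood includes the change-of-variables
#' Jacobian so AIC values are comparable across families, and the affine
#' map is recorded in `params`.
#'
#' @param values numeric vector, length >= 4.
#' @return A data.frame with columns `family`, `log_likelihood`, `aic`,
#'   `fit_ok` and a list-column `params`, ordered by ascending AIC (fitted
#'   families first).
#' @export
fit_candidates <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("need at least 4 values", call. = FALSE)
  fits <- list(
    normal = fit_family_fitdistrplus(values, "norm", k = 2),
    uniform = fit_family_uniform(values),
    exponential = fit_family_positive(values, "exp", k = 1, strict = FALSE),
    logistic = fit_family_fitdistrplus(values, "logis", k = 2),
    beta = fit_family_beta(values),
    lognormal = fit_family_positive(values, "lnorm", k = 2, strict = TRUE),
    gamma = fit_family_positive(values, "gamma", k = 2, strict = TRUE)
  )
  out <- data.frame(
    family = names(fits),
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    aic = vapply(fits, `[[`, 0, "aic"),
    fit_ok = vapply(fits, `[[`, FALSE, "fit_ok"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$params <- I(lapply(fits, `[[`, "params"))
  if (!any(out$fit_ok)) stop("no candidate family could be fitted", call. = FALSE)
  out[order(!out$fit_ok, out$aic), , drop = FALSE]
}

fit_family_fitdistrplus <- function(values, dist, k) {
  fit <- tryCatch(
    fitdistrplus::fitdist(values, dist, method = "mle"),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$loglik)) {
    return(list(log_likelihood = -Inf, aic = Inf, fit_ok = FALSE,
                params = list()))
  }
  list(log_likelihood = fit$loglik, aic = 2 * k - 2 * fit$loglik,
       fit_ok = TRUE, params = as.list(fit$estimate))
}

fit_family_positive <- function(values, dist, k, strict) {
  bad <- if (strict) any(values <= 0) else any(values < 0)
  if (bad) {
    return(list(log_likelihood = -Inf, aic = Inf, fit_ok = FALSE,
                params = list()))
  }
  fit_family_fitdistrplus(values, dist, k)
}

fit_family_uniform <- function(values) {
  # MLE is the sample range; boundary case, handled in closed form
  a <- min(values)
  b <- max(values)
  if (a == b) {
    return(list(log_likelihood = -Inf, aic = Inf, fit_ok = FALSE,
                params = list()))
  }
  ll <- -length(values) * log(b - a)
  list(log_likelihood = ll, aic = 2 * 2 - 2 * ll, fit_ok = TRUE,
       params = list(min = a, max = b))
}

fit_family_beta <- function(values) {
  rng <- range(values)
  span <- diff(rng)
  if (span == 0) {
    return(list(log_likelihood = -Inf, aic = Inf, fit_ok = FALSE,
                params = list()))
  }
  # affine map onto (0, 1) with a 0.5% margin keeping endpoints interior
  offset <- rng[1] - 0.005 * span
  scale <- span * 1.01
  y <- (values - offset) / scale
  fit <- tryCatch(fitdistrplus::fitdist(y, "beta", method = "mle"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$loglik)) {
    return(list(log_likelihood = -Inf, aic = Inf, fit_ok = FALSE,
                params = list(rescale_offset = offset, rescale_scale = scale)))
  }
  # Jacobian of the affine map, so AIC is comparable on the original scale
  ll <- fit$loglik - length(values) * log(scale)
  list(log_likelihood = ll, aic = 2 * 2 - 2 * ll, fit_ok = TRUE,
       params = c(as.list(fit$estimate),
                  list(rescale_offset = offset, rescale_scale = scale)))
}

#' Q-Q points against a fitted normal
#'
#' Pairs the i-th ordered value with the fitted normal quantile at
#' probability (i - 0.5) / n. Points near the diagonal indicate a good fit.
#'
#' @param values numeric vector.
#' @param fit a [normal_fit].
#' @return A data.frame with columns `theoretical`, `empirical`, sorted
#'   ascending in both.
#' @export
qq_points <- function(values, fit) {
  stopifnot(inherits(fit, "normal_fit"))
  if (!is.finite(fit$sigma_hat) || fit$sigma_hat <= 0) {
    stop("degenerate fit", call. = FALSE)
  }
  emp <- sort(as.numeric(values))
  n <- length(emp)
  p <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = qnorm(p, mean = fit$mu_hat, sd = fit$sigma_hat),
             empirical = emp)
}
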