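unit_fit <- function() {
  # exact mu = 0, sigma = 1 fit for scoring already-standardized values
  structure(list(mu_hat = 0, sigma2_hat = 1, sigma_hat = 1, n = 36,
                 log_likelihood = 0), class = "normal_fit")
}

test_that("z_scores standardizes and calls strictly below threshold", {
  fit <- unit_fit()
  calls <- z_scores(c(0, -2.00, -0.45, -0.92, -0.91), fit, threshold = -0.91)
  expect_equal(calls$z, c(0, -2.00, -0.45, -0.92, -0.91))
  expect_equal(calls$call,
               c("negative", "positive", "negative", "positive", "negative"))
  # x at the control mean scores zero
  f2 <- fit_normal_mle(c(10, 12, 14))
  expect_equal(z_scores(12, f2)$z, 0)
  expect_error(z_scores(1, structure(list(mu_hat = 0, sigma_hat = 0),
                                     class = "normal_fit")), "degenerate")
})

test_that("the bundled SCA3 validation cohort yields 9/11 positive calls", {
  bench <- sca3_benchmark()
  expect_equal(nrow(bench), 11)
  calls <- z_scores(bench$zscore, unit_fit(), threshold = -0.91,
                    sample_ids = bench$patient_id, locus_id = "SCA3")
  expect_equal(sum(calls$call == "positive"), 9)
  expect_equal(calls$call[calls$sample_id == "B042"], "positive") # z -0.92
  expect_equal(calls$call[calls$sample_id == "A001"], "negative") # z -0.86
})

test_that("ROC handles separation, symmetry, and small instances exactly", {
  r1 <- roc_curve(c(-3, -2), c(0, 1))
  expect_equal(r1$auc, 1)
  r2 <- roc_curve(c(-1, 0, 2), c(-1, 0, 2))
  expect_equal(r2$auc, 0.5)
  # 3 of 4 pairs correctly ordered
  r3 <- roc_curve(c(-2, -1), c(0, -1.5))
  expect_equal(r3$auc, 3 / 4)
  expect_equal(r3$auc, auc_pair_oracle(c(-2, -1), c(0, -1.5)))
  expect_error(roc_curve(numeric(0), c(1, 2)), "at least one")
  expect_warning(r4 <- roc_curve(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(r4$auc, 0.5)
})

test_that("Mann-Whitney AUC equals trapezoid and pair enumeration", {
  set.seed(55)
  for (i in 1:100) {
    n1 <- sample(2:12, 1); n0 <- sample(2:15, 1)
    cs <- round(rnorm(n1, -1), 1) # rounding forces ties
    ks <- round(rnorm(n0, 0), 1)
    r <- roc_curve(cs, ks)
    expect_equal(r$auc, auc_trapezoid(r), tolerance = 1e-12)
    if (n1 <= 10) {
      expect_equal(r$auc, auc_pair_oracle(cs, ks), tolerance = 1e-12)
    }
  }
})

test_that("AUC agrees with an established ROC library", {
  skip_if_not_installed("pROC")
  set.seed(56)
  cs <- rnorm(11, -1.5); ks <- rnorm(36, 0)
  r <- roc_curve(cs, ks)
  ref <- pROC::roc(response = rep(c(1, 0), c(11, 36)),
                   predictor = c(cs, ks), direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("select_threshold balances sensitivity and specificity", {
  r <- roc_curve(c(-3, -2), c(0, 1))
  t <- select_threshold(r)
  expect_gt(t, -2); expect_lt(t, 0)
  expect_equal(mean(c(-3, -2) < t), 1)
  expect_equal(mean(c(0, 1) >= t), 1)
  # identical multisets: every midpoint ties; smallest wins
  r_tie <- roc_curve(c(-1, 0, 2), c(-1, 0, 2))
  expect_equal(select_threshold(r_tie), -0.5)
})

test_that("select_threshold equals the exhaustive midpoint scan", {
  set.seed(60)
  for (i in 1:5) {
    cs <- rnorm(80, -1.2)
    ks <- rnorm(120, 0)
    r <- roc_curve(cs, ks)
    expect_equal(select_threshold(r), threshold_scan_oracle(cs, ks))
  }
})

test_that("Wald test: null identity, hand-computed value, scale invariance", {
  w0 <- wald_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$wald_statistic, 0)
  expect_equal(w0$p_value, 1)

  w <- wald_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$wald_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$wald_statistic, -3.6742346142, tolerance = 1e-9)
  expect_equal(w$p_value, 2.385635e-04, tolerance = 1e-6)

  w_scaled <- wald_group_test(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(w_scaled$wald_statistic, w$wald_statistic, tolerance = 1e-12)
  expect_equal(w_scaled$p_value, w$p_value, tolerance = 1e-12)

  expect_error(wald_group_test(c(1), c(1, 2)), "at least 2")
  expect_error(wald_group_test(c(2, 2), c(3, 3)), "variances")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("calling is monotone: lower depth never rescues a positive", {
  set.seed(80)
  fit <- fit_normal_mle(rnorm(36, 100, 10))
  x <- seq(40, 160, by = 5)
  calls <- z_scores(x, fit)$call
  # once negative (high depth), all higher depths stay negative
  first_neg <- match("negative", calls)
  expect_true(all(calls[seq_along(calls) >= first_neg] == "negative"))
  expect_true(all(calls[seq_len(first_neg - 1)] == "positive"))
})

test_that("depth_test reports per-locus Wald results with BH q-values", {
  co <- simulate_cohort(sim_config(seed = 5))
  norm <- normalize_counts(co$counts)
  res <- depth_test(norm)
  expect_equal(res$locus_id, rownames(norm))
  expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))
  # the expanded locus shows suppressed case depth
  sca3 <- res[res$locus_id == "SCA3", ]
  expect_lt(sca3$mean_case, sca3$mean_control)
  expect_lt(sca3$p_value, 1e-3)
  expect_equal(res$q_value[!is.na(res$p_value)],
               bh_oracle(res$p_value[!is.na(res$p_value)]))
})

test_that("call_locus pools controls and supports leave-one-out", {
  co <- simulate_cohort(sim_config(seed = 6))
  norm <- normalize_counts(co$counts)
  res <- call_locus(norm, "SCA3")
  expect_s3_class(res$fit, "normal_fit")
  expect_equal(res$fit$n, 36)
  expect_equal(nrow(res$calls), 47)
  res_loo <- call_locus(norm, "SCA3", leave_one_out = TRUE)
  is_ctrl <- co$counts$label == "control"
  expect_false(all(res_loo$calls$z[is_ctrl] == res$calls$z[is_ctrl]))
  expect_equal(res_loo$calls$z[!is_ctrl], res$calls$z[!is_ctrl])
  expect_error(call_locus(norm, "NOPE"), "not found")
})
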