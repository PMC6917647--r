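#' Z-score expansion calls at one locus
#'
#' Standardizes each sample's normalized count against the control-cohort
#' fit, `z = (x - mu_hat) / sigma_hat`, and calls a sample expansion-positive
#' when its Z-score falls strictly below the threshold. Depth suppression at
#' an expanded locus makes Z strongly negative, so "below threshold" means
#' "depth too low to be a normal-length allele". The default threshold of
#' -0.91 is the ROC balance point calibrated on the SCA3 validation cohort
#' bundled with the package.
#'
#' @param x numeric vector of normalized counts at one locus (named by
#'   sample, or supply `sample_ids`).
#' @param fit a [normal_fit] of the control cohort at the same locus.
#' @param threshold calling cutoff on the Z scale (default -0.91).
#' @param sample_ids sample identifiers.
#' @param locus_id optional locus identifier carried into the output.
#' @return A data.frame with columns `sample_id`, `locus_id`, `z`,
#'   `threshold`, `call` (`"positive"`/`"negative"`).
#' @export
z_scores <- function(x, fit, threshold = -0.91,
                     sample_ids = names(x), locus_id = NA_character_) {
  stopifnot(inherits(fit, "normal_fit"))
  if (!is.finite(fit$sigma_hat) || fit$sigma_hat <= 0) {
    stop("degenerate fit: sigma_hat must be positive", call. = FALSE)
  }
  x <- as.numeric(x)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_along(x))
  z <- (x - fit$mu_hat) / fit$sigma_hat
  if (any(!is.finite(z))) stop("non-finite Z-score", call. = FALSE)
  data.frame(sample_id = sample_ids, locus_id = locus_id, z = z,
             threshold = threshold,
             call = ifelse(z < threshold, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit controls and call every sample at one locus
#'
#' Convenience wrapper: fits the normal model to the control samples'
#' normalized counts at `locus` and Z-scores all samples against it.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param locus locus identifier (row of `norm`).
#' @param label per-sample labels; defaults to the `label` attribute of
#'   `norm`.
#' @param threshold calling cutoff (default -0.91).
#' @param leave_one_out when `TRUE`, each control sample is scored against
#'   a fit that excludes it; default `FALSE` (pooled controls).
#' @return A list with elements `fit` ([normal_fit]) and `calls`
#'   (the [z_scores()] data.frame).
#' @export
call_locus <- function(norm, locus, label = attr(norm, "label"),
                       threshold = -0.91, leave_one_out = FALSE) {
  if (!locus %in% rownames(norm)) {
    stop("locus '", locus, "' not found in normalized matrix", call. = FALSE)
  }
  x <- norm[locus, ]
  is_control <- label == "control"
  if (sum(is_control) < 2) {
    stop("need at least 2 control samples to fit", call. = FALSE)
  }
  fit <- fit_normal_mle(x[is_control])
  calls <- z_scores(x, fit, threshold = threshold,
                    sample_ids = colnames(norm), locus_id = locus)
  if (leave_one_out) {
    for (i in which(is_control)) {
      loo <- fit_normal_mle(x[setdiff(which(is_control), i)])
      zi <- (x[i] - loo$mu_hat) / loo$sigma_hat
      calls$z[i] <- zi
      calls$call[i] <- if (zi < threshold) "positive" else "negative"
    }
  }
  list(fit = fit, calls = calls)
}

#' ROC curve for a lower-is-positive score
#'
#' Sweeps thresholds over the midpoints of adjacent distinct observed
#' scores (plus sentinels beyond the extremes); at each threshold t,
#' sensitivity is the fraction of case scores strictly below t and
#' specificity the fraction of control scores not below t. The AUC is
#' computed by the rank (Mann-Whitney) formulation with ties counted 1/2 --
#' the probability that a random case scores below a random control -- which
#' equals trapezoidal integration of the empirical step curve.
#'
#' @param case_scores,control_scores numeric score vectors (e.g. Z-scores);
#'   lower scores indicate the positive (expanded) class.
#' @return A list of class `str_roc`: `points` (data.frame of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_cases`, `n_controls`.
#' @export
roc_curve <- function(case_scores, control_scores) {
  case_scores <- as.numeric(case_scores)
  control_scores <- as.numeric(control_scores)
  if (!length(case_scores) || !length(control_scores)) {
    stop("need at least one case and one control score", call. = FALSE)
  }
  pooled <- sort(unique(c(case_scores, control_scores)))
  mids <- if (length(pooled) > 1) {
    (pooled[-1] + pooled[-length(pooled)]) / 2
  } else {
    numeric(0)
  }
  thresholds <- c(pooled[1] - 1, mids, pooled[length(pooled)] + 1)
  sens <- vapply(thresholds, function(t) mean(case_scores < t), 0)
  spec <- vapply(thresholds, function(t) mean(control_scores >= t), 0)
  n1 <- length(case_scores)
  n0 <- length(control_scores)
  if (length(pooled) == 1) {
    warning("all scores identical; AUC set to 0.5", call. = FALSE)
    auc <- 0.5
  } else {
    # U = #{case > control} + 0.5 #{ties}; AUC = P(case < control) + 0.5 P(=)
    r <- rank(c(case_scores, control_scores))
    u_case_high <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    auc <- 1 - u_case_high / (n1 * n0)
  }
  structure(list(points = data.frame(threshold = thresholds,
                                     sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_cases = n1, n_controls = n0),
            class = "str_roc")
}

#' @export
print.str_roc <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls, AUC = %.3f (%d thresholds)\n",
              x$n_cases, x$n_controls, x$auc, nrow(x$points)))
  invisible(x)
}

#' Balanced ("turning-point") threshold from a ROC curve
#'
#' Returns the candidate threshold minimizing |sensitivity - specificity|,
#' the operating point where the two error rates balance. Ties are broken
#' by maximizing Youden's J (sensitivity + specificity - 1), then by the
#' smaller threshold. Candidates are the midpoints between adjacent
#' distinct observed scores (the interior thresholds of [roc_curve()]),
#' so the returned cutoff never coincides with an observed score.
#'
#' @param roc an `str_roc` from [roc_curve()].
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "str_roc"))
  pts <- roc$points
  if (nrow(pts) > 2) pts <- pts[-c(1, nrow(pts)), , drop = FALSE] # interior midpoints
  balance <- abs(pts$sensitivity - pts$specificity)
  youden <- pts$sensitivity + pts$specificity - 1
  ord <- order(balance, -youden, pts$threshold)
  pts$threshold[ord[1]]
}

#' Two-group Wald test of mean normalized depth
#'
#' Compares case and control mean normalized counts with the Wald statistic
#' `W = (mean_case - mean_control) / sqrt(s2_case/n_case + s2_ctrl/n_ctrl)`
#' using unbiased (n - 1) group variances, with a two-sided p-value from
#' the standard normal reference.
#'
#' @param case_values,control_values numeric vectors, length >= 2 each.
#' @return A list of class `wald_test`: `mean_case`, `mean_control`,
#'   `wald_statistic`, `p_value`.
#' @export
wald_group_test <- function(case_values, control_values) {
  case_values <- as.numeric(case_values)
  control_values <- as.numeric(control_values)
  if (length(case_values) < 2 || length(control_values) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  v1 <- var(case_values)
  v0 <- var(control_values)
  if (v1 == 0 && v0 == 0) {
    stop("both group variances are zero", call. = FALSE)
  }
  se <- sqrt(v1 / length(case_values) + v0 / length(control_values))
  w <- (mean(case_values) - mean(control_values)) / se
  structure(list(mean_case = mean(case_values),
                 mean_control = mean(control_values),
                 wald_statistic = w,
                 p_value = 2 * pnorm(-abs(w))),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald test: mean case %.4g vs control %.4g, W = %.3f, p = %.3g\n",
              x$mean_case, x$mean_control, x$wald_statistic, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment across tested loci, via
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Per-locus Wald depth test with BH correction
#'
#' Runs [wald_group_test()] at every locus of a normalized matrix
#' (cases vs controls by label) and adjusts the p-values across loci with
#' [bh_adjust()]. Loci where both group variances vanish get `NA`
#' statistics.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param label per-sample labels; defaults to the `label` attribute.
#' @return A data.frame with columns `locus_id`, `mean_case`,
#'   `mean_control`, `wald_statistic`, `p_value`, `q_value`.
#' @export
depth_test <- function(norm, label = attr(norm, "label")) {
  is_case <- label == "case"
  is_control <- label == "control"
  if (sum(is_case) < 2 || sum(is_control) < 2) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  rows <- lapply(rownames(norm), function(l) {
    res <- tryCatch(wald_group_test(norm[l, is_case], norm[l, is_control]),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(locus_id = l, mean_case = mean(norm[l, is_case]),
                 mean_control = mean(norm[l, is_control]),
                 wald_statistic = NA_real_, p_value = NA_real_)
    } else {
      data.frame(locus_id = l, mean_case = res$mean_case,
                 mean_control = res$mean_control,
                 wald_statistic = res$wald_statistic, p_value = res$p_value)
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  out
}
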