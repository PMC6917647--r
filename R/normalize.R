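#' TMM scale factors for a count matrix
#'
#' Computes trimmed-mean-of-M-values (TMM) scale factors across the cohort.
#' The reference sample is the one whose upper-quartile count fraction is
#' closest to the cohort mean; each sample's factor is two to the weighted
#' trimmed mean of per-locus log2 count ratios against the reference (M
#' values), trimming the most extreme `trim_m` of M values and `trim_a` of
#' average-abundance (A) values, with inverse binomial-variance precision
#' weights. Loci with a zero count in either member of a pair drop out of
#' that pair's mean. Factors are re-centered so their geometric mean is 1.
#'
#' The computation is delegated to [edgeR::calcNormFactors()], the reference
#' implementation of the method.
#'
#' @param x an [str_counts] object with at least 2 samples and at least 2
#'   loci that are nonzero in at least 2 samples.
#' @param trim_m fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @return A named numeric vector of class `tmm_factors` (one positive
#'   factor per sample, geometric mean 1) with attributes
#'   `reference_sample`, `trim_m`, `trim_a`.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(x, "str_counts"))
  counts <- x$counts
  if (ncol(counts) < 2) {
    stop("TMM needs at least 2 samples", call. = FALSE)
  }
  usable_loci <- rowSums(counts > 0) >= 2
  if (sum(usable_loci) < 2) {
    stop("TMM needs at least 2 loci with nonzero counts in at least 2 samples",
         call. = FALSE)
  }
  all_zero <- colSums(counts) == 0
  if (any(all_zero)) {
    stop("all-zero sample(s): ", paste(x$samples[all_zero], collapse = ", "),
         call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, lib.size = x$lib_size, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  # upper-quartile reference rule, reported for provenance
  f75 <- apply(counts, 2, quantile, probs = 0.75) / x$lib_size
  ref <- x$samples[which.min(abs(f75 - mean(f75)))]
  structure(setNames(as.numeric(f), x$samples),
            reference_sample = ref, trim_m = trim_m, trim_a = trim_a,
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM scale factors (reference: ", attr(x, "reference_sample"), ")\n",
      sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Normalize a count matrix to CPM of effective library size
#'
#' Divides each count by its sample's effective library size (library size
#' times TMM factor) and scales to counts per million:
#' `x[l, s] = counts[l, s] / (lib_size[s] * factor[s]) * 1e6`.
#' These normalized counts are the input to control-model fitting and
#' Z-score calling.
#'
#' @param x an [str_counts] object.
#' @param factors a [tmm_factors] vector covering all samples of `x`;
#'   computed from `x` by default.
#' @return A numeric loci-by-samples matrix with the same dimnames as
#'   `x$counts` and attributes `loci` and `label` carried over from `x`.
#' @export
normalize_counts <- function(x, factors = tmm_factors(x)) {
  stopifnot(inherits(x, "str_counts"))
  if (!all(x$samples %in% names(factors))) {
    stop("factors must cover every sample of the count matrix", call. = FALSE)
  }
  eff <- x$lib_size * as.numeric(factors[x$samples])
  if (any(!is.finite(eff) | eff <= 0)) {
    stop("zero or non-finite effective library size", call. = FALSE)
  }
  norm <- sweep(x$counts, 2, eff, "/") * 1e6
  attr(norm, "loci") <- x$loci
  attr(norm, "label") <- x$label
  norm
}
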