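# Independent oracles used across the suite. Each deliberately re-derives
# its quantity from first principles (direct formulas, brute-force
# enumeration) rather than calling the package's own code path.

# Direct implementation of the trimmed weighted mean of M-values:
# reference by upper-quartile rule, per-locus log2 ratios trimmed by rank,
# inverse binomial-variance weights, factors re-centered to geometric mean 1.
tmm_oracle <- function(counts, lib, trim_m = 0.3, trim_a = 0.05) {
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    obs <- counts[, j] / lib[j]
    rf <- counts[, ref] / lib[ref]
    M <- log2(obs / rf)
    A <- (log2(obs) + log2(rf)) / 2
    w <- (lib[j] - counts[, j]) / (lib[j] * counts[, j]) +
      (lib[ref] - counts[, ref]) / (lib[ref] * counts[, ref])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, 0)
  f / exp(mean(log(f)))
}

# AUC by exhaustive case-control pair enumeration (lower case score = hit).
auc_pair_oracle <- function(case_scores, control_scores) {
  pairs <- outer(case_scores, control_scores,
                 function(a, b) (a < b) + 0.5 * (a == b))
  mean(pairs)
}

# Trapezoidal integration of the ROC step curve.
auc_trapezoid <- function(roc) {
  x <- 1 - roc$points$specificity
  y <- roc$points$sensitivity
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Benjamini-Hochberg step-up written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive threshold scan with the same balance/Youden/smallest objective.
threshold_scan_oracle <- function(case_scores, control_scores) {
  pooled <- sort(unique(c(case_scores, control_scores)))
  mids <- (pooled[-1] + pooled[-length(pooled)]) / 2
  best <- NULL
  for (t in mids) {
    sens <- mean(case_scores < t)
    spec <- mean(control_scores >= t)
    cand <- c(abs(sens - spec), -(sens + spec - 1), t)
    if (is.null(best) ||
        isTRUE(cand[1] < best[1]) ||
        (cand[1] == best[1] && cand[2] < best[2]) ||
        (cand[1] == best[1] && cand[2] == best[2] && cand[3] < best[3])) {
      best <- cand
    }
  }
  best[3]
}

# --- SAM fixture builders -------------------------------------------------

sam_header <- function(chroms, len = 100000L, sorted = TRUE) {
  c(paste0("@HD\tVN:1.6\tSO:", if (sorted) "coordinate" else "unknown"),
    paste0("@SQ\tSN:", chroms, "\tLN:", len))
}

sam_read <- function(qname, chrom, pos, len = 100L, flag = 0L) {
  paste(qname, flag, chrom, pos, 60, paste0(len, "M"), "*", 0, 0,
        strrep("A", len), strrep("I", len), sep = "\t")
}

write_sam <- function(records, chroms, path = tempfile(fileext = ".sam"),
                      sorted = TRUE) {
  writeLines(c(sam_header(chroms, sorted = sorted), records), path)
  path
}

# Brute-force per-read, per-locus overlap enumeration on simple xM-CIGAR
# SAM text: distinct qnames whose [pos, pos + len - 1] hits [start+1, end].
count_oracle <- function(sam_path, loci) {
  lines <- readLines(sam_path)
  recs <- lines[!startsWith(lines, "@")]
  f <- strsplit(recs, "\t")
  qname <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  chrom <- vapply(f, `[[`, "", 3)
  pos <- as.integer(vapply(f, `[[`, "", 4))
  len <- as.integer(sub("M$", "", vapply(f, `[[`, "", 6)))
  mapped <- bitwAnd(flag, 4L) == 0L
  counts <- integer(nrow(loci))
  for (l in seq_len(nrow(loci))) {
    hit <- mapped & chrom == loci$chrom[l] &
      pos <= loci$end[l] & (pos + len - 1) >= (loci$start[l] + 1)
    counts[l] <- length(unique(qname[hit]))
  }
  setNames(counts, loci$locus_id)
}

# Tiny cohort used where full study dimensions would be overkill.
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(sim_config(n_controls = 8, n_cases = 4, n_loci = 5,
                             target_depth = 80, seed = seed, ...))
}

# One end-to-end run: normalize, fit controls at the expanded locus,
# score everyone, return Z-scores split by truth plus the ROC.
pipeline_scores <- function(cohort) {
  norm <- normalize_counts(cohort$counts)
  locus <- cohort$counts$loci$locus_id[cohort$config$expanded_locus]
  res <- call_locus(norm, locus, label = cohort$counts$label)
  z <- setNames(res$calls$z, res$calls$sample_id)
  list(z_case = z[cohort$truth], z_control = z[!cohort$truth],
       roc = roc_curve(z[cohort$truth], z[!cohort$truth]))
}
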