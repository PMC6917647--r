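#' Configuration for a synthetic STR-panel cohort
#'
#' Defaults mirror the design of the validation study the package's
#' calibration targets: 36 controls and 11 expansion cases screened over
#' the ten classic CAG/CTG repeat disorders (DRPLA, DM1, DM2, SCA1, SCA2,
#' SCA3, SCA6, SCA7, SCA8, SCA12), a capture panel sequenced to about 200x
#' at each locus, and a halving of expected depth at the expanded locus in
#' cases (the GC/mappability suppression mechanism, abstracted to a single
#' multiplicative factor).
#'
#' @param n_controls,n_cases cohort sizes (controls >= 2).
#' @param n_loci number of STR loci on the panel.
#' @param target_depth expected reads per locus per unit library multiplier.
#' @param libsize_cv coefficient of variation of the lognormal per-sample
#'   library-size multiplier (mean 1).
#' @param suppression factor in (0, 1\] multiplying expected depth at the
#'   expanded locus in cases; 1 means no signal.
#' @param dispersion negative-binomial dispersion of raw counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param expanded_locus index of the expanded locus; defaults to the SCA3
#'   position when `n_loci = 10`, else 1.
#' @param locus_weight per-locus capture-efficiency weights (default all 1).
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 36, n_cases = 11, n_loci = 10,
                       target_depth = 200, libsize_cv = 0.3,
                       suppression = 0.5, dispersion = 0.05,
                       expanded_locus = NULL,
                       locus_weight = rep(1, n_loci), seed = 1) {
  panel <- c("DRPLA", "DM1", "DM2", "SCA1", "SCA2", "SCA3", "SCA6", "SCA7",
             "SCA8", "SCA12")
  if (is.null(expanded_locus)) {
    expanded_locus <- if (n_loci == 10) match("SCA3", panel) else 1L
  }
  cfg <- list(n_controls = n_controls, n_cases = n_cases, n_loci = n_loci,
              target_depth = target_depth, libsize_cv = libsize_cv,
              suppression = suppression, dispersion = dispersion,
              expanded_locus = as.integer(expanded_locus),
              locus_weight = locus_weight,
              locus_names = if (n_loci == 10) panel else
                sprintf("locus%02d", seq_len(n_loci)),
              seed = as.integer(seed))
  stopifnot(cfg$n_controls >= 2, cfg$n_cases >= 0, cfg$n_loci >= 1,
            cfg$target_depth > 0, cfg$libsize_cv >= 0,
            cfg$suppression > 0, cfg$suppression <= 1,
            cfg$dispersion >= 0,
            cfg$expanded_locus >= 1, cfg$expanded_locus <= cfg$n_loci,
            length(cfg$locus_weight) == cfg$n_loci, all(cfg$locus_weight > 0))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a synthetic STR-panel cohort
#'
#' Draws a per-sample library-size multiplier from a lognormal with mean 1
#' and the configured coefficient of variation; the expected count at locus
#' l for sample s is `target_depth * multiplier_s * locus_weight_l`, scaled
#' by the suppression factor when s is a case and l is the expanded locus.
#' Raw counts are negative-binomial with the configured dispersion
#' (Poisson when dispersion = 0). Library sizes are the column sums.
#' Deterministic under a fixed seed.
#'
#' @param config a [sim_config].
#' @return A list of class `sim_cohort`: `counts` (an [str_counts] with
#'   labels filled in), `truth` (named logical, `TRUE` for expanded
#'   samples), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_controls + config$n_cases
  sample_ids <- c(sprintf("ctrl%02d", seq_len(config$n_controls)),
                  if (config$n_cases > 0)
                    sprintf("case%02d", seq_len(config$n_cases)))
  label <- rep(c("control", "case"), c(config$n_controls, config$n_cases))
  is_case <- label == "case"
  # loci spaced 10 kb apart on one synthetic chromosome, 1 kb wide
  loci <- str_loci(
    locus_id = config$locus_names,
    chrom = "chrS",
    start = (seq_len(config$n_loci) - 1L) * 10000L,
    end = (seq_len(config$n_loci) - 1L) * 10000L + 1000L,
    repeat_unit = "CAG",
    disease_label = config$locus_names
  )
  counts <- withr::with_seed(config$seed, {
    sdlog <- sqrt(log(1 + config$libsize_cv^2))
    mult <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mu <- outer(config$locus_weight * config$target_depth, mult)
    mu[config$expanded_locus, is_case] <-
      mu[config$expanded_locus, is_case] * config$suppression
    draw <- if (config$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      rpois(length(mu), lambda = mu)
    }
    matrix(draw, nrow = config$n_loci, ncol = n)
  })
  lib <- colSums(counts)
  if (any(lib == 0)) lib[lib == 0] <- 1 # guard: pathological tiny-depth draws
  structure(list(
    counts = str_counts(counts, loci, lib, label, samples = sample_ids),
    truth = setNames(is_case, sample_ids),
    config = config
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d controls + %d cases, %d loci, depth %g, suppression %g at '%s' (seed %d)\n",
    x$config$n_controls, x$config$n_cases, x$config$n_loci,
    x$config$target_depth, x$config$suppression,
    x$counts$loci$locus_id[x$config$expanded_locus], x$config$seed))
  invisible(x)
}

#' Emit per-sample SAM files reproducing a simulated cohort
#'
#' Writes one coordinate-sorted single-end SAM file per sample, tiling each
#' locus with as many reads as its simulated count. Reads are placed fully
#' inside their locus (cycling across the tileable positions), so
#' [count_reads()] on the output reproduces the simulated matrix
#' cell-for-cell and the loci-region library sizes equal the column sums.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param read_length read length in bases (must fit inside every locus).
#' @return Named character vector of SAM paths, invisibly.
#' @export
emit_sam <- function(cohort, dir, read_length = 100) {
  stopifnot(inherits(cohort, "sim_cohort"))
  loci <- cohort$counts$loci
  if (any(loci$end - loci$start < read_length)) {
    stop("read_length exceeds a locus width", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chrom_len <- max(loci$end) + 1000L
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", unique(loci$chrom), "\tLN:", chrom_len))
  seq_str <- strrep("A", read_length)
  qual_str <- strrep("I", read_length)
  cigar <- paste0(read_length, "M")
  paths <- setNames(
    file.path(dir, paste0(cohort$counts$samples, ".sam")),
    cohort$counts$samples
  )
  for (s in seq_along(paths)) {
    recs <- character(0)
    for (l in seq_len(nrow(loci))) {
      n_reads <- cohort$counts$counts[l, s]
      if (n_reads == 0) next
      first <- loci$start[l] + 1L # 1-based SAM position
      span <- loci$end[l] - loci$start[l] - read_length + 1L
      pos <- sort(first + (seq_len(n_reads) - 1L) %% span)
      recs <- c(recs, sprintf(
        "%s_L%02d_r%05d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
        cohort$counts$samples[s], l, seq_len(n_reads), loci$chrom[l], pos,
        cigar, seq_str, qual_str))
    }
    writeLines(c(header, recs), paths[s])
  }
  invisible(paths)
}
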