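---
title: "Depth-based STR expansion calling: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based STR expansion calling: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strdepth)
```

## The signal and the model

Capture panels that tile known repeat loci sequence them to high depth
(about 200x in the design this package targets). When a sample carries a
large CAG expansion at a locus, two physical effects reduce the number of
reads the pipeline assigns there: the expanded fragment's higher GC content
biases both capture and sequencing against it, and reads from the expanded
tract mismatch the reference enough to lose mappability. strdepth models
the consequence, not the mechanism: the *normalized* read count of a
sample at the locus, compared against a control cohort, drops when the
locus is expanded.

The pipeline is deliberately simple and each stage is inspectable:

1. **Counting** (`count_reads()`): distinct read names overlapping each
   locus by at least one base. Counting is "non-unique all": a read
   overlapping two loci is credited to both, because ambiguity between
   adjacent repeat targets is itself informative coverage and dropping
   such reads would deepen the very depth loss we are trying to measure
   at exactly the loci where it is not wanted. Secondary and supplementary
   alignments are kept (the read name still counts once per locus); strand
   is ignored since depth is strand-agnostic; the minimum overlap is one
   base. Coordinates are BED half-open throughout.

2. **Normalization** (`tmm_factors()`, `normalize_counts()`): the count
   matrix is scaled per sample by library size times a
   trimmed-mean-of-M-values (TMM) factor, then put on a counts-per-million
   scale. TMM is delegated to edgeR's reference implementation with the
   method's published defaults — 30% trim on log-ratios, 5% on
   abundances, upper-quartile reference rule — and the factors are
   re-centered to geometric mean 1 so the normalization is identifiable.
   The CPM scale itself is a free choice: Z-scores are invariant to any
   common rescaling, so nothing downstream depends on it. The library
   size can be computed over the panel loci (default) or over all mapped
   reads; both are exposed because a depth denominator restricted to few
   loci is more sensitive to the expansion itself, while an all-mapped
   denominator needs the whole alignment.

3. **Control model** (`fit_normal_mle()`): the control cohort's normalized
   counts at the locus are fitted to a normal distribution by maximum
   likelihood in closed form. The variance estimator uses the **n
   denominator** — the true MLE — rather than the n−1 sample variance,
   and the Z-scores divide by exactly this σ̂. With 36 controls the
   difference is a 1.4% scale factor; we keep the MLE form for fidelity
   to the method as specified. A fit with zero variance (all controls
   identical) is refused as degenerate rather than producing infinite
   Z-scores.

4. **Calling** (`z_scores()`): z = (x − μ̂)/σ̂, positive call iff
   z < threshold, *strictly*. "Below the threshold" is read as strict
   inequality; at the calibrated cutoff −0.91 the bundled validation
   cohort contains scores of −0.92 (called) and −0.86 (not called), which
   is consistent with either convention, so the choice is documented
   rather than data-determined.

## Why normal? The diagnostics

The normal family is not assumed blindly. `moments_diagnostics()` places
the control sample on the skewness–kurtosis plane (Pearson kurtosis,
normal = 3) with seeded bootstrap resamples (default 100; the count is a
display choice, not an inferential one), and `fit_candidates()` fits seven
families — normal, uniform, exponential, logistic, beta, lognormal,
gamma — by maximum likelihood and ranks them by AIC. Two families need
care:

* **Uniform** has a boundary MLE (the sample min/max), fitted in closed
  form with log-likelihood −n·log(max − min).
* **Beta** requires support in (0, 1); the data are mapped by the affine
  transform onto that interval with a 0.5% margin keeping the endpoints
  interior, and the reported log-likelihood includes the Jacobian of the
  map so the AIC is comparable with the other families on the original
  scale. The affine parameters are recorded with the fit.

Families whose support the data violate (negative values for
exponential/lognormal/gamma) are flagged unfittable instead of silently
dropped. `qq_points()` pairs ordered values with fitted quantiles at
probabilities (i − 0.5)/n for the usual visual check. No formal
goodness-of-fit test is run; family choice is by AIC plus diagnostics.

## Threshold calibration

`roc_curve()` sweeps candidate thresholds over the midpoints between
adjacent distinct observed scores (plus sentinels beyond the extremes).
Midpoints avoid the degenerate question of whether a threshold equal to an
observed score includes it. Sensitivity at t is the fraction of case
scores strictly below t; specificity the fraction of control scores at or
above t. The AUC is computed by the Mann–Whitney rank formulation with
ties counted one half — the probability that a random case scores below a
random control — which is algebraically equal to trapezoidal integration
of the empirical ROC step curve; the test suite asserts that equality on
random instances rather than trusting it.

`select_threshold()` operationalizes the "turning point where sensitivity
and specificity are best balanced" as the candidate minimizing
|sensitivity − specificity|, with ties broken first by maximizing Youden's
J and then by taking the smaller threshold, making the rule deterministic
on tied or degenerate inputs.

## The group test

`wald_group_test()` compares case and control mean normalized depth with
W = (mean_case − mean_control)/√(s²_case/n_case + s²_ctrl/n_ctrl), using
unbiased group variances and a standard-normal reference, and
`depth_test()` applies it per locus with Benjamini–Hochberg correction
across loci (via `stats::p.adjust`). With small case groups (n ≈ 11) the
normal reference is mildly anticonservative relative to a
Welch-t reference — simulation at the package's own design point puts the
empirical type-I rate near 0.07 at nominal 0.05. The form is kept because
it is the specified test, the statistic is exposed, and the screen's
calling decisions do not run through it; treat its p-values as
descriptive.

## The simulator: what it emulates and what it does not

`simulate_cohort()` generates the study conditions the calibration
targets: 36 controls and 11 cases over the ten classic CAG/CTG repeat
loci (DRPLA, DM1, DM2, SCA1, SCA2, SCA3, SCA6, SCA7, SCA8, SCA12),
target depth 200, with the SCA3 locus suppressed to 50% expected depth in
cases. Per-sample library-size variation is lognormal with mean 1 and
coefficient of variation 0.3 — a value chosen once as typical of capture
library yield spread; neither smaller (0.1) nor larger (0.5) values change
the pipeline's qualitative behavior since TMM absorbs the variation. Raw
counts are negative-binomial with dispersion 0.05 (Poisson at dispersion
0): the model only requires the *normalized* counts to look normal across
controls, and moderate-dispersion NB counts reproduce that after
normalization. Suppression is a single multiplicative factor on expected
depth — it abstracts the GC/mappability mechanism and does not model a GC
curve, probe-specific capture weights (configurable but defaulting to 1),
read-level repeat sequence, or paired-end structure. `emit_sam()` writes
single-end reads tiled inside each locus, which is sufficient for the
counting contract but intentionally unrealistic as sequence data.

Passing tests on these cohorts therefore demonstrate that the pipeline
recovers a multiplicative depth suppression under realistic count noise
and library-size variation; they do not demonstrate robustness to GC
waves, batch effects between capture runs, or loci whose control depth is
itself multimodal.

## Validation sizes and numerical choices

The test suite and the acceptance script validate end-to-end recovery on
100 simulated cohorts at the design point above (mean AUC ≥ 0.9, balanced
sensitivity and specificity ≥ 0.8 — bracketing the calibrated method's
reported 0.928/0.88/0.82 operating point) and null calibration on 200
suppression-free cohorts; these sizes give Monte-Carlo standard errors
comfortably below the margins being asserted while keeping the default
run fast. TMM factors are asserted against an independent direct
implementation of the trimmed weighted mean to 1e-9; MLE identities to
1e-12; AUC dualities to 1e-12.

Degenerate inputs are errors, not warnings: zero library sizes, all-zero
samples, identical control values, empty ROC groups. The one soft case is
a ROC over completely identical score multisets, which warns and reports
AUC 0.5.

## Known limitations

* Binary screen only: no repeat-length estimate, no heterozygous/
  homozygous distinction.
* One locus is modeled at a time against pooled controls (a leave-one-out
  mode exists for scoring control samples themselves); a control cohort
  contaminated by undetected carriers will inflate σ̂ and cost
  sensitivity.
* The default threshold −0.91 was calibrated on one cohort and one panel
  design; new panels should recalibrate via `roc_curve()` +
  `select_threshold()` on their own labeled data.
* Depth suppression is not specific to expansions — capture batch
  effects, CNVs or poor-quality libraries can mimic it; positives need
  orthogonal confirmation (repeat-primed PCR).
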