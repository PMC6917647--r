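#' The bundled SCA3 validation cohort
#'
#' Eleven patients molecularly confirmed as SCA3, with the repeat-expansion
#' prediction and p-value produced by the empirical-distribution caller
#' exSTRa on the same capture data, and the depth Z-score at the SCA3 locus
#' from the method this package implements. At the calibrated threshold of
#' -0.91, 9 of the 11 Z-scores are called positive (sensitivity 0.82);
#' exSTRa flagged an expansion in 7 of 11, all of them loci in the
#' CAG-expansion class.
#'
#' @return A data.frame with columns `patient_id`, `original_diagnosis`,
#'   `exstra_prediction` (comma-separated locus names, `NA` when no call),
#'   `exstra_p`, `zscore`.
#' @export
sca3_benchmark <- function() {
  path <- system.file("extdata", "sca3_benchmark.tsv", package = "strdepth")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA")
}

#' CAG-class repeat-expansion loci
#'
#' Disorders whose pathogenic expansion is a CAG tract (or, for SCA8, the
#' bidirectionally transcribed CTG.CAG tract), i.e. the class an
#' SCA3-driven misprediction is expected to fall into because of shared
#' repeat content.
#'
#' @return Character vector of locus names.
#' @export
cag_class_loci <- function() {
  c("HD", "DRPLA", "SCA1", "SCA2", "SCA3", "SCA6", "SCA7", "SCA8", "SCA12",
    "SCA17")
}
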