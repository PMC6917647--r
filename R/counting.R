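#' Count reads over STR loci
#'
#' For each sample, counts the number of distinct read names with at least
#' one aligned segment overlapping each locus by one or more bases. A read
#' overlapping two loci is credited to both ("non-unique all" counting);
#' paired segments and secondary or supplementary alignments of the same
#' read name still count once per locus. Unmapped reads are ignored; strand
#' is ignored.
#'
#' The per-sample library size is the number of distinct counted read names
#' over a stated region set: by default the provided loci themselves,
#' or every mapped read in the file with `library_region = "all_mapped"`.
#'
#' @param files character vector of SAM or BAM paths, one per sample. SAM
#'   files are converted to temporary BAM internally.
#' @param loci an [str_loci] table.
#' @param sample_ids sample identifiers; defaults to file base names.
#' @param label per-sample labels (`"control"`, `"case"`, `"unknown"`).
#' @param library_region `"loci"` (default) or `"all_mapped"`.
#' @return An [str_counts] object.
#' @export
count_reads <- function(files, loci,
                        sample_ids = tools::file_path_sans_ext(basename(files)),
                        label = rep("unknown", length(files)),
                        library_region = c("loci", "all_mapped")) {
  library_region <- match.arg(library_region)
  validate_str_loci(loci)
  gr <- loci_granges(loci)
  res <- lapply(files, count_one_sample, gr = gr,
                library_region = library_region)
  counts <- vapply(res, `[[`, numeric(nrow(loci)), "counts")
  counts <- matrix(counts, nrow = nrow(loci),
                   dimnames = list(loci$locus_id, sample_ids))
  lib <- vapply(res, `[[`, numeric(1), "lib_size")
  zero <- which(lib <= 0)
  if (length(zero)) {
    stop("zero library size for sample(s): ",
         paste(sample_ids[zero], collapse = ", "), call. = FALSE)
  }
  mode(counts) <- "integer"
  str_counts(counts, loci, lib, label, samples = sample_ids)
}

count_one_sample <- function(file, gr, library_region) {
  bam <- as_bam(file)
  hdr_seqs <- tryCatch(
    names(Rsamtools::scanBamHeader(bam)[[1]]$targets),
    error = function(e) stop("unreadable alignment source '", file, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_chr <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                         hdr_seqs)
  if (length(missing_chr)) {
    warning("chromosome(s) absent from alignment header of '", basename(file),
            "' (counted as zero): ", paste(missing_chr, collapse = ", "),
            call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  qname <- S4Vectors::mcols(aln)$qname
  ov <- GenomicRanges::findOverlaps(gr, GenomicRanges::granges(aln),
                                    minoverlap = 1L)
  per_locus <- split(qname[S4Vectors::subjectHits(ov)],
                     factor(S4Vectors::queryHits(ov), levels = seq_along(gr)))
  counts <- vapply(per_locus, function(q) length(unique(q)), 0)
  lib_size <- if (library_region == "loci") {
    length(unique(qname[S4Vectors::subjectHits(ov)]))
  } else {
    length(unique(qname))
  }
  list(counts = counts, lib_size = lib_size)
}

as_bam <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    file
  }
}
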