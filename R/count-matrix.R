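#' Construct a loci-by-samples count matrix
#'
#' The central container of the pipeline: a matrix of non-negative integer
#' read counts with STR loci as rows and samples as columns, together with a
#' per-sample library size (the depth-normalization denominator) and a
#' per-sample cohort label.
#'
#' @param counts integer matrix, loci x samples, non-negative.
#' @param loci an [str_loci] table with one row per matrix row.
#' @param lib_size positive numeric, one per sample: total counted reads
#'   over the stated region set.
#' @param label per-sample label, one of `"control"`, `"case"`, `"unknown"`.
#' @param samples sample identifiers; defaults to `colnames(counts)`.
#'
#' @return A list of class `str_counts` with elements `counts`, `loci`,
#'   `samples`, `lib_size`, `label`.
#' @export
str_counts <- function(counts, loci, lib_size,
                       label = rep("unknown", ncol(counts)),
                       samples = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(counts)))
  if (nrow(counts) != nrow(loci)) {
    stop("counts has ", nrow(counts), " rows but loci table has ", nrow(loci),
         call. = FALSE)
  }
  if (length(lib_size) != ncol(counts)) {
    stop("lib_size length (", length(lib_size), ") != number of samples (",
         ncol(counts), ")", call. = FALSE)
  }
  if (length(label) != ncol(counts)) {
    stop("label length (", length(label), ") != number of samples (",
         ncol(counts), ")", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, ]
    stop("counts must be non-negative integers; offending cell [",
         loci$locus_id[bad[1]], ", ", samples[bad[2]], "] = ",
         counts[bad[1], bad[2]], call. = FALSE)
  }
  if (any(!is.finite(lib_size) | lib_size <= 0)) {
    stop("every library size must be a positive number", call. = FALSE)
  }
  if (!all(label %in% c("control", "case", "unknown"))) {
    stop("labels must be 'control', 'case' or 'unknown'", call. = FALSE)
  }
  validate_str_loci(loci)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(loci$locus_id, samples)
  structure(
    list(counts = counts, loci = loci, samples = as.character(samples),
         lib_size = setNames(as.numeric(lib_size), samples),
         label = setNames(as.character(label), samples)),
    class = "str_counts"
  )
}

#' @export
print.str_counts <- function(x, ...) {
  cat("str_counts: ", nrow(x$counts), " loci x ", ncol(x$counts), " samples (",
      sum(x$label == "control"), " control, ", sum(x$label == "case"),
      " case, ", sum(x$label == "unknown"), " unknown)\n", sep = "")
  cat("library sizes: ", paste(format(range(x$lib_size), digits = 4),
                               collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.str_counts <- function(x) dim(x$counts)

#' Write a count matrix and its sample metadata to TSV
#'
#' The counts file has a header row (`locus_id` followed by sample ids) and
#' one row per locus; the metadata file has columns `sample_id`,
#' `library_size`, `label`. Both carry a `#`-prefixed provenance header.
#' `read_count_matrix()` on the pair reproduces the object exactly.
#'
#' @param x an [str_counts] object.
#' @param counts_file,meta_file output paths.
#' @param loci_file optional path to also write the locus table
#'   (see [write_loci()]).
#' @return `counts_file`, invisibly.
#' @export
write_count_matrix <- function(x, counts_file, meta_file, loci_file = NULL) {
  stopifnot(inherits(x, "str_counts"))
  hdr <- paste0("# strdepth ", utils::packageVersion("strdepth"), " count matrix")
  con <- file(counts_file, "w")
  writeLines(c(hdr, paste(c("locus_id", x$samples), collapse = "\t")), con)
  write.table(cbind(locus_id = rownames(x$counts), as.data.frame(x$counts)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  con <- file(meta_file, "w")
  writeLines(c(hdr, "sample_id\tlibrary_size\tlabel"), con)
  write.table(data.frame(x$samples, x$lib_size, x$label), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  if (!is.null(loci_file)) write_loci(x$loci, loci_file)
  invisible(counts_file)
}

#' Read a count matrix and its sample metadata from TSV
#'
#' @param counts_file TSV written by [write_count_matrix()] (or matching its
#'   layout: header row of `locus_id` + sample ids, integer counts).
#' @param meta_file TSV with columns `sample_id`, `library_size`, `label`.
#' @param loci an optional [str_loci] table; when `NULL`, a minimal locus
#'   table with placeholder coordinates is built from the row identifiers.
#' @return An [str_counts] object.
#' @export
read_count_matrix <- function(counts_file, meta_file, loci = NULL) {
  tab <- read.delim(counts_file, comment.char = "#", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2 || names(tab)[1] != "locus_id") {
    stop("counts file must have a 'locus_id' column followed by sample columns",
         call. = FALSE)
  }
  samples <- names(tab)[-1]
  counts_chr <- as.matrix(tab[, -1, drop = FALSE])
  counts <- suppressWarnings(matrix(as.numeric(counts_chr), nrow = nrow(tab)))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at [", tab$locus_id[bad[1, 1]], ", ",
         samples[bad[1, 2]], "]: '", counts_chr[bad[1, 1], bad[1, 2]], "'",
         call. = FALSE)
  }
  meta <- read.delim(meta_file, comment.char = "#", check.names = FALSE)
  need <- c("sample_id", "library_size", "label")
  if (!all(need %in% names(meta))) {
    stop("metadata file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  missing_meta <- setdiff(samples, meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing for sample(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(samples, meta$sample_id), ]
  if (anyNA(meta$library_size)) {
    stop("missing library_size for sample(s): ",
         paste(meta$sample_id[is.na(meta$library_size)], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(loci)) {
    loci <- str_loci(tab$locus_id, chrom = "unknown",
                     start = seq_len(nrow(tab)) * 1000L - 1000L,
                     end = seq_len(nrow(tab)) * 1000L)
  } else {
    loci <- loci[match(tab$locus_id, loci$locus_id), ]
    if (anyNA(loci$locus_id)) {
      stop("counts file contains loci absent from the supplied locus table",
           call. = FALSE)
    }
    class(loci) <- c("str_loci", "data.frame")
  }
  mode(counts) <- "integer"
  str_counts(counts, loci, meta$library_size, as.character(meta$label),
             samples = samples)
}
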