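#' Write / read a normalized matrix as TSV
#'
#' Same layout as the count matrix TSV (header `locus_id` + sample ids,
#' `#`-prefixed provenance lines) but with real-valued entries.
#'
#' @param norm matrix from [normalize_counts()].
#' @param file path.
#' @return `file` (write) or the numeric matrix (read), invisibly for write.
#' @export
write_normalized <- function(norm, file) {
  con <- file(file, "w")
  writeLines(c(paste0("# strdepth ", utils::packageVersion("strdepth"),
                      " normalized matrix (CPM of effective library size)"),
               paste(c("locus_id", colnames(norm)), collapse = "\t")), con)
  write.table(cbind(locus_id = rownames(norm),
                    as.data.frame(format(norm, digits = 12, trim = TRUE))),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(file)
}

#' @rdname write_normalized
#' @param meta_file optional metadata TSV (as in [read_count_matrix()]) used
#'   to attach per-sample labels.
#' @export
read_normalized <- function(file, meta_file = NULL) {
  tab <- read.delim(file, comment.char = "#", check.names = FALSE)
  if (names(tab)[1] != "locus_id") {
    stop("normalized file must start with a 'locus_id' column", call. = FALSE)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$locus_id
  if (!is.null(meta_file)) {
    meta <- read.delim(meta_file, comment.char = "#")
    attr(m, "label") <- setNames(
      as.character(meta$label[match(colnames(m), meta$sample_id)]),
      colnames(m))
  }
  m
}
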