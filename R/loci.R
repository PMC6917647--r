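#' Construct a table of STR loci
#'
#' An `str_loci` table holds one row per short-tandem-repeat locus:
#' an identifier, a genomic interval in BED convention (0-based start,
#' exclusive end), the repeat unit and a free-text disease label.
#'
#' @param locus_id character, unique locus identifiers.
#' @param chrom character, chromosome names.
#' @param start integer, 0-based inclusive start positions.
#' @param end integer, 0-based exclusive end positions (`start < end`).
#' @param repeat_unit character, repeat motif over A/C/G/T (e.g. `"CAG"`);
#'   may be `NA` when unknown.
#' @param disease_label character, free-text label (e.g. `"SCA3"`); may be
#'   `NA`.
#'
#' @return A `data.frame` of class `str_loci` with the six columns above.
#' @seealso [read_loci()] to load loci from a BED-like file.
#' @export
#' @examples
#' str_loci("SCA3", "chr14", 92070000L, 92071000L, "CAG", "SCA3")
str_loci <- function(locus_id, chrom, start, end,
                     repeat_unit = NA_character_,
                     disease_label = NA_character_) {
  loci <- data.frame(
    locus_id = as.character(locus_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    repeat_unit = as.character(rep_len(repeat_unit, length(locus_id))),
    disease_label = as.character(rep_len(disease_label, length(locus_id))),
    stringsAsFactors = FALSE
  )
  validate_str_loci(loci)
  class(loci) <- c("str_loci", "data.frame")
  loci
}

validate_str_loci <- function(loci) {
  if (anyNA(loci$start) || anyNA(loci$end)) {
    stop("locus coordinates must be integer and non-missing", call. = FALSE)
  }
  bad <- which(loci$start >= loci$end)
  if (length(bad)) {
    stop("locus '", loci$locus_id[bad[1]], "': start (", loci$start[bad[1]],
         ") must be < end (", loci$end[bad[1]], ")", call. = FALSE)
  }
  dup <- duplicated(loci$locus_id)
  if (any(dup)) {
    stop("duplicate locus_id: ", paste(unique(loci$locus_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  ru <- loci$repeat_unit[!is.na(loci$repeat_unit)]
  if (length(ru) && any(!grepl("^[ACGT]+$", ru))) {
    stop("repeat_unit must be a non-empty string over {A,C,G,T}", call. = FALSE)
  }
  invisible(loci)
}

#' Read STR loci from a BED-like file
#'
#' Parses a tab- or whitespace-delimited table with columns chrom, start,
#' end, name, and optionally repeat_unit (column 5) and disease_label
#' (column 6). Coordinates follow the BED convention: 0-based start,
#' exclusive end. Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param file path to the BED-like file.
#' @return An [str_loci] table in file order.
#' @export
read_loci <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(str_loci(character(), character(), integer(), integer()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  parse_row <- function(i) {
    f <- fields[[i]]
    if (length(f) < 4) {
      stop("line ", idx[i], ": expected at least 4 columns (chrom, start, end, name), got ",
           length(f), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", idx[i], ": non-integer coordinate in '", lines[idx[i]], "'",
           call. = FALSE)
    }
    list(chrom = f[1], start = start, end = end, locus_id = f[4],
         repeat_unit = if (length(f) >= 5) f[5] else NA_character_,
         disease_label = if (length(f) >= 6) f[6] else NA_character_)
  }
  rows <- lapply(seq_along(idx), parse_row)
  str_loci(
    locus_id = vapply(rows, `[[`, "", "locus_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) r$start, 0L),
    end = vapply(rows, function(r) r$end, 0L),
    repeat_unit = vapply(rows, `[[`, "", "repeat_unit"),
    disease_label = vapply(rows, `[[`, "", "disease_label")
  )
}

#' Write STR loci to a BED-like file
#'
#' @param loci an [str_loci] table.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_loci <- function(loci, file) {
  validate_str_loci(loci)
  out <- loci[, c("chrom", "start", "end", "locus_id", "repeat_unit",
                  "disease_label")]
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = ".")
  invisible(file)
}

loci_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    locus_id = loci$locus_id
  )
}
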