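#' Read a genome index (FASTA .fai dialect)
#'
#' Parses the first two columns (chromosome name and length, in bp) of a
#' FASTA index file. Any additional `.fai` columns (byte offset, line bases,
#' line width) are accepted and ignored, so real `samtools faidx` output can
#' be consumed directly. Record order is preserved and defines the canonical
#' chromosome sort order used by every downstream stage (split tables,
#' gathered call sets, region classification).
#'
#' @param path Path to a whitespace- or tab-separated index file with at
#'   least two columns per line.
#' @return A tibble with columns `chrom` (character) and `length` (double,
#'   bp), one row per chromosome in file order.
#' @examples
#' fai <- tempfile(fileext = ".fai")
#' writeLines(c("Chr01\t43270923", "Chr02\t35937250"), fai)
#' read_genome_index(fai)
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) {
    stop("genome index file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("genome index is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  records <- purrr::imap(fields, function(f, i) {
    if (length(f) < 2) {
      stop("line ", i, " of ", path, " has fewer than 2 columns", call. = FALSE)
    }
    len <- suppressWarnings(as.numeric(f[[2]]))
    if (is.na(len) || len != trunc(len)) {
      stop("line ", i, " of ", path, ": length '", f[[2]],
           "' is not an integer", call. = FALSE)
    }
    if (len < 1) {
      stop("line ", i, " of ", path, ": non-positive length ", len,
           call. = FALSE)
    }
    tibble::tibble(chrom = f[[1]], length = len)
  })
  index <- dplyr::bind_rows(records)
  dup <- index$chrom[duplicated(index$chrom)]
  if (length(dup) > 0) {
    first_dup_line <- which(index$chrom == dup[[1]])[2]
    stop("duplicate chromosome name '", dup[[1]], "' at line ",
         first_dup_line, " of ", path, call. = FALSE)
  }
  genome_index(index$chrom, index$length)
}

#' Construct a genome index from vectors
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Numeric vector of chromosome lengths in bp (each >= 1).
#' @return A validated tibble with columns `chrom` and `length`.
#' @export
genome_index <- function(chrom, length) {
  idx <- tibble::tibble(chrom = as.character(chrom),
                        length = as.numeric(length))
  validate_genome_index(idx)
  idx
}

validate_genome_index <- function(index) {
  if (!all(c("chrom", "length") %in% names(index))) {
    stop("a genome index needs `chrom` and `length` columns", call. = FALSE)
  }
  if (nrow(index) == 0) stop("genome index is empty", call. = FALSE)
  if (any(!nzchar(index$chrom)) || anyNA(index$chrom)) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(index$chrom)) {
    stop("duplicate chromosome name '",
         index$chrom[duplicated(index$chrom)][1], "'", call. = FALSE)
  }
  if (anyNA(index$length) || any(index$length < 1) ||
      any(index$length != trunc(index$length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  invisible(index)
}

#' Write a genome index as two tab-separated columns
#'
#' @param index A genome index tibble (see [read_genome_index()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(index, path) {
  validate_genome_index(index)
  writeLines(paste(index$chrom, format(index$length, scientific = FALSE,
                                       trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Largest chromosome of a genome index
#'
#' The chunk-length calculation anchors on the longest chromosome. Ties are
#' broken by index order (the first maximal record wins).
#'
#' @inheritParams write_genome_index
#' @return A one-row tibble with `chrom` and `length`.
#' @export
largest_chromosome <- function(index) {
  validate_genome_index(index)
  index[which.max(index$length), c("chrom", "length")]
}
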