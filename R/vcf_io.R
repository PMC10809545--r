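#' Read a VCF file into a record tibble
#'
#' Parsing is delegated to [vcfR::read.vcfR()]; the result is flattened to
#' one row per record with the eight fixed columns in lower case
#' (`chrom`, `pos`, `id`, `ref`, `alt`, `qual`, `filter`, `info`), a
#' `format` column, and one character column of per-sample entries for each
#' sample. Missing fixed fields (`.`) become `NA`. The raw `##` header
#' lines are kept in the `header` attribute so they can be written back
#' out; sample names are in the `samples` attribute.
#'
#' @param path Path to a VCF file (plain or gzip).
#' @return A tibble of variant records.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  meta <- v@meta
  samples <- character(0)
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) > 1) samples <- colnames(gt)[-1]
  if (nrow(v@fix) == 0) {
    rec <- tibble::tibble(
      chrom = character(0), pos = numeric(0), id = character(0),
      ref = character(0), alt = character(0), qual = numeric(0),
      filter = character(0), info = character(0), format = character(0)
    )
    for (s in samples) rec[[s]] <- character(0)
  } else {
    fix <- tibble::as_tibble(v@fix)
    rec <- tibble::tibble(
      chrom = fix$CHROM,
      pos = as.numeric(fix$POS),
      id = fix$ID,
      ref = fix$REF,
      alt = fix$ALT,
      qual = suppressWarnings(as.numeric(fix$QUAL)),
      filter = fix$FILTER,
      info = fix$INFO
    )
    if (!is.null(gt) && ncol(gt) >= 1) {
      rec$format <- unname(gt[, 1])
      for (s in samples) rec[[s]] <- unname(gt[, s])
    } else {
      rec$format <- NA_character_
    }
  }
  new_vcf_records(rec, header = meta, samples = samples)
}

new_vcf_records <- function(rec, header, samples) {
  attr(rec, "header") <- header
  attr(rec, "samples") <- samples
  rec
}

#' Sample names of a VCF record tibble
#'
#' @param variants A tibble from [read_vcf()] (or shaped like one).
#' @return Character vector of sample column names.
#' @export
vcf_samples <- function(variants) {
  s <- attr(variants, "samples")
  if (!is.null(s)) return(s)
  fixed <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "info",
             "format")
  setdiff(names(variants), fixed)
}

vcf_header_or_default <- function(variants, contigs = NULL) {
  h <- attr(variants, "header")
  if (is.null(h) || length(h) == 0) {
    h <- "##fileformat=VCFv4.2"
    if (!is.null(contigs)) {
      h <- c(h, sprintf("##contig=<ID=%s,length=%s>", contigs$chrom,
                        format(contigs$length, scientific = FALSE,
                               trim = TRUE)))
    }
  }
  h
}

#' Write a VCF record tibble to disk
#'
#' Emits the `##` header lines (from the `header` attribute unless
#' overridden), the `#CHROM` column line, and one tab-separated line per
#' record. `NA` fixed fields are written as `.`.
#'
#' @param variants A VCF record tibble.
#' @param path Output path (plain text).
#' @param header Optional character vector of `##` lines to use instead of
#'   the tibble's own.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, header = NULL) {
  samples <- vcf_samples(variants)
  if (is.null(header)) header <- vcf_header_or_default(variants)
  dot <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x), ".", x)
  }
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO",
                      if (length(samples) > 0) c("FORMAT", samples)),
                    collapse = "\t")
  body <- character(0)
  if (nrow(variants) > 0) {
    cols <- list(
      variants$chrom,
      format(variants$pos, scientific = FALSE, trim = TRUE),
      dot(variants$id), variants$ref, dot(variants$alt),
      dot(variants$qual), dot(variants$filter), dot(variants$info)
    )
    if (length(samples) > 0) {
      cols <- c(cols, list(dot(variants$format)),
                lapply(samples, function(s) dot(variants[[s]])))
    }
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  writeLines(c(header, col_line, body), path)
  invisible(path)
}

#' Contigs declared in a VCF header
#'
#' @param variants A VCF record tibble with a `header` attribute.
#' @return A tibble with `chrom` and `length` (NA when not declared).
#' @export
vcf_contigs <- function(variants) {
  h <- attr(variants, "header")
  ctg <- h[grepl("^##contig=", h)]
  if (length(ctg) == 0) {
    return(tibble::tibble(chrom = character(0), length = numeric(0)))
  }
  ids <- stringr::str_match(ctg, "ID=([^,>]+)")[, 2]
  lens <- suppressWarnings(as.numeric(stringr::str_match(ctg,
                                                         "length=([0-9]+)")[, 2]))
  tibble::tibble(chrom = ids, length = lens)
}
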