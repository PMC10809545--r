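#' Default hard-filter thresholds
#'
#' The six cutoffs of the SNP hard-filter disjunction
#' `QUAL < 30.0 || QD < 2.0 || MQ < 20.0 || MQRankSum < -3.0 ||
#' ReadPosRankSum < -3.0 || DP < 5.0`: a site fails a condition when the
#' annotation is present and strictly below the cutoff.
#'
#' @param qual Phred-scaled site quality cutoff.
#' @param qd Quality-by-depth cutoff.
#' @param mq RMS mapping quality cutoff.
#' @param mq_rank_sum Mapping-quality rank-sum z-score cutoff.
#' @param read_pos_rank_sum Read-position rank-sum z-score cutoff.
#' @param dp Combined read depth cutoff.
#' @return Named numeric vector of cutoffs.
#' @export
hard_filter_thresholds <- function(qual = 30.0, qd = 2.0, mq = 20.0,
                                   mq_rank_sum = -3.0,
                                   read_pos_rank_sum = -3.0, dp = 5.0) {
  c(qual = qual, qd = qd, mq = mq, mq_rank_sum = mq_rank_sum,
    read_pos_rank_sum = read_pos_rank_sum, dp = dp)
}

# maps annotation column -> reason code reported in FILTER
.filter_codes <- c(qual = "QUAL", qd = "QD", mq = "MQ",
                   mq_rank_sum = "MQRankSum",
                   read_pos_rank_sum = "ReadPosRankSum", dp = "DP")

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  m
}

#' Extract the six filterable annotations from VCF records
#'
#' Reads `QUAL` from the quality column and `QD`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum`, `DP` from the INFO field. Absent keys become `NA`
#' (missing), which under the default filter semantics can never fail a
#' condition.
#'
#' @param variants A VCF record tibble.
#' @return A tibble with numeric columns `qual`, `qd`, `mq`,
#'   `mq_rank_sum`, `read_pos_rank_sum`, `dp`.
#' @export
site_annotations <- function(variants) {
  parse_num <- function(raw, key) {
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "." & is.na(val))
    if (length(bad) > 0) {
      stop("non-numeric ", key, " value '", raw[bad[1]], "' at ",
           variants$chrom[bad[1]], ":",
           format(variants$pos[bad[1]], scientific = FALSE), call. = FALSE)
    }
    val
  }
  tibble::tibble(
    qual = variants$qual,
    qd = parse_num(info_field(variants$info, "QD"), "QD"),
    mq = parse_num(info_field(variants$info, "MQ"), "MQ"),
    mq_rank_sum = parse_num(info_field(variants$info, "MQRankSum"),
                            "MQRankSum"),
    read_pos_rank_sum = parse_num(info_field(variants$info,
                                             "ReadPosRankSum"),
                                  "ReadPosRankSum"),
    dp = parse_num(info_field(variants$info, "DP"), "DP")
  )
}

#' Evaluate the hard-filter disjunction on site annotations
#'
#' A condition fails iff its annotation is present and strictly below its
#' cutoff; the site fails iff any condition fails. Missing annotations
#' never fail a condition by default (the conventional treatment of absent
#' annotations); set `missing_fails = TRUE` to make a missing annotation
#' fail its condition instead.
#'
#' @param ann A tibble from [site_annotations()] (columns `qual`, `qd`,
#'   `mq`, `mq_rank_sum`, `read_pos_rank_sum`, `dp`).
#' @param thresholds Named cutoffs, see [hard_filter_thresholds()].
#' @param missing_fails Treat a missing annotation as failing its
#'   condition.
#' @return A tibble with `passed` (logical) and `reasons` (list column of
#'   failed-condition codes, in fixed QUAL, QD, MQ, MQRankSum,
#'   ReadPosRankSum, DP order; empty iff passed).
#' @examples
#' hard_filter(tibble::tibble(qual = 29.9, qd = 5, mq = 40,
#'                            mq_rank_sum = 0, read_pos_rank_sum = 0,
#'                            dp = 10))
#' @export
hard_filter <- function(ann, thresholds = hard_filter_thresholds(),
                        missing_fails = FALSE) {
  stopifnot(all(names(.filter_codes) %in% names(ann)))
  if (nrow(ann) == 0) {
    return(tibble::tibble(passed = logical(0), reasons = list()))
  }
  fail <- sapply(names(.filter_codes), function(col) {
    x <- ann[[col]]
    f <- !is.na(x) & x < thresholds[[col]]
    if (missing_fails) f <- f | is.na(x)
    f
  })
  fail <- matrix(fail, nrow = nrow(ann),
                 dimnames = list(NULL, names(.filter_codes)))
  reasons <- apply(fail, 1, function(f) unname(.filter_codes[f]),
                   simplify = FALSE)
  tibble::tibble(passed = rowSums(fail) == 0, reasons = reasons)
}

#' Keep pure SNP sites only
#'
#' A site is kept iff its REF is a single base (A/C/G/T) and every ALT
#' allele is a single base; multiallelic all-SNP sites are kept, and any
#' site with an indel, symbolic or breakend allele is dropped whole.
#'
#' @param variants A VCF record tibble.
#' @return The SNP-only subset, order preserved.
#' @export
select_snps <- function(variants) {
  is_base <- function(x) !is.na(x) & grepl("^[ACGTacgt]$", x)
  alt_ok <- vapply(strsplit(ifelse(is.na(variants$alt), "", variants$alt),
                            ",", fixed = TRUE),
                   function(a) length(a) > 0 && all(is_base(a)), logical(1))
  keep <- is_base(variants$ref) & alt_ok
  out <- variants[keep, ]
  new_vcf_records(out, attr(variants, "header"), vcf_samples(variants))
}

#' Apply the SNP hard filter to a record stream
#'
#' In `"flag"` mode the FILTER column of every record is set to `PASS` or
#' to the semicolon-joined codes of the failed conditions; in
#' `"pass_only"` mode only passing records are emitted. Record order is
#' preserved either way.
#'
#' @param variants A VCF record tibble.
#' @param emit `"flag"` or `"pass_only"`.
#' @inheritParams hard_filter
#' @return A VCF record tibble.
#' @export
apply_filters <- function(variants, emit = c("flag", "pass_only"),
                          thresholds = hard_filter_thresholds(),
                          missing_fails = FALSE) {
  emit <- match.arg(emit)
  samples <- vcf_samples(variants)
  hdr <- attr(variants, "header")
  if (nrow(variants) == 0) return(variants)
  verdict <- hard_filter(site_annotations(variants), thresholds,
                         missing_fails)
  if (emit == "flag") {
    variants$filter <- ifelse(
      verdict$passed, "PASS",
      vapply(verdict$reasons, paste, character(1), collapse = ";"))
    new_vcf_records(variants, hdr, samples)
  } else {
    new_vcf_records(variants[verdict$passed, ], hdr, samples)
  }
}
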