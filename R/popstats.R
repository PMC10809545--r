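#' @keywords internal
#' Parse GT strings into per-call allele index lists
#'
#' Accepts diploid ("0/1", "1|1"), haploid ("1") and partially missing
#' ("./1") calls; missing alleles are dropped, so a haploid or partial
#' call contributes the alleles it actually carries.
#' @noRd
parse_gt_alleles <- function(gt) {
  gt <- sub(":.*$", "", gt)
  lapply(strsplit(gt, "[/|]"), function(a) {
    a <- suppressWarnings(as.integer(a[a != "." & a != "" & !is.na(a)]))
    a[!is.na(a)]
  })
}

site_allele_counts <- function(variants) {
  samples <- vcf_samples(variants)
  if (length(samples) == 0) {
    stop("the record tibble carries no sample columns", call. = FALSE)
  }
  gt <- lapply(samples, function(s) parse_gt_alleles(variants[[s]]))
  purrr::map(seq_len(nrow(variants)), function(i) {
    unlist(lapply(gt, function(sample_calls) sample_calls[[i]]))
  })
}

#' Minor allele frequency per site
#'
#' Allele frequencies are computed over the non-missing called alleles
#' (two per complete diploid call, one per haploid or half-missing call);
#' the MAF is the frequency of the second most common allele, 0 for a
#' monomorphic site, and `NA` when every call at the site is missing.
#'
#' @param variants A multi-sample VCF record tibble.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `n_alleles`
#'   (non-missing called alleles) and `maf`.
#' @export
site_maf <- function(variants) {
  counts <- site_allele_counts(variants)
  maf <- vapply(counts, function(a) {
    if (length(a) == 0) return(NA_real_)
    freq <- sort(tabulate(a + 1L), decreasing = TRUE) / length(a)
    if (length(freq) < 2) 0 else freq[2]
  }, numeric(1))
  tibble::tibble(chrom = variants$chrom, pos = variants$pos,
                 ref = variants$ref, alt = variants$alt,
                 n_alleles = lengths(counts), maf = maf)
}

#' Accession support per site
#'
#' The number of samples (accessions) carrying at least one non-reference
#' allele at each site; a homozygous-alt sample counts once, and missing
#' calls contribute nothing.
#'
#' @param variants A multi-sample VCF record tibble.
#' @return A tibble with `chrom`, `pos` and `support`.
#' @export
accession_support <- function(variants) {
  samples <- vcf_samples(variants)
  if (length(samples) == 0) {
    stop("the record tibble carries no sample columns", call. = FALSE)
  }
  carrier <- sapply(samples, function(s) {
    vapply(parse_gt_alleles(variants[[s]]), function(a) any(a > 0),
           logical(1))
  })
  carrier <- matrix(carrier, nrow = nrow(variants))
  tibble::tibble(chrom = variants$chrom, pos = variants$pos,
                 support = rowSums(carrier))
}

#' Validate sites by minimum accession support
#'
#' Counts how many sites are carried by at least `min_support` accessions
#' — the check used to corroborate novel SNPs against a large resequencing
#' panel (three or more carriers by default).
#'
#' @param variants A multi-sample VCF record tibble (one row per site).
#' @param min_support Minimum number of carrier accessions (>= 1).
#' @return A one-row tibble with `n_sites`, `n_validated`, `fraction`.
#' @export
support_validation <- function(variants, min_support = 3) {
  if (nrow(variants) == 0) stop("no sites to validate", call. = FALSE)
  if (min_support < 1) stop("`min_support` must be >= 1", call. = FALSE)
  supp <- accession_support(variants)$support
  tibble::tibble(n_sites = nrow(variants),
                 n_validated = sum(supp >= min_support),
                 fraction = sum(supp >= min_support) / nrow(variants))
}

#' Round half away from zero
#'
#' Fixed-precision rounding where exact .5 ties go up (e.g. 0.125 -> 0.13
#' at 2 digits), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize gene presence and allele status across accessions
#'
#' For a gene that is entirely absent from part of a population, each
#' accession is either gene-absent or carries one of the named alleles at
#' a diagnostic site. Counts are reported per category together with the
#' percentage of all accessions (present + absent), rounded half-up to two
#' decimals.
#'
#' @param status Tibble with one row per accession: `accession`,
#'   `gene_present` (logical) and `allele` (character allele label for
#'   gene-present accessions, `NA` for gene-absent ones).
#' @return A tibble of class `allele_status_summary` with `category`
#'   (`"absent"` first, then allele labels), `n`, and `percent`.
#' @examples
#' status <- tibble::tibble(
#'   accession = paste0("acc", 1:8),
#'   gene_present = c(rep(FALSE, 4), rep(TRUE, 4)),
#'   allele = c(rep(NA, 4), "tolerant", rep("intolerant", 3)))
#' allele_status_summary(status)
#' @export
allele_status_summary <- function(status) {
  bad <- which(!status$gene_present & !is.na(status$allele))
  if (length(bad) > 0) {
    stop("accession '", status$accession[bad[1]],
         "' is gene-absent but carries an allele label", call. = FALSE)
  }
  missing_lab <- which(status$gene_present & is.na(status$allele))
  if (length(missing_lab) > 0) {
    stop("gene-present accession '", status$accession[missing_lab[1]],
         "' has no allele label", call. = FALSE)
  }
  n_total <- nrow(status)
  category <- ifelse(status$gene_present, status$allele, "absent")
  out <- dplyr::count(tibble::tibble(category = category), .data$category,
                      name = "n")
  out <- out[order(out$category != "absent", out$category), ]
  out$percent <- round_half_up(out$n / n_total * 100, 2)
  out <- tibble::as_tibble(out)
  attr(out, "n_total") <- n_total
  class(out) <- c("allele_status_summary", class(tibble::tibble()))
  out
}

#' @export
tidy.allele_status_summary <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot an allele-status summary
#'
#' @param object An `allele_status_summary` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.allele_status_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$percent,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of accessions",
                  title = "Gene presence / allele status") +
    ggplot2::theme_minimal()
}

#' Subset variants to those inside a set of regions
#'
#' A variant is included iff its 1-based position lies inside any region.
#' Regions given as a BED path are converted from 0-based half-open to
#' 1-based inclusive; a tibble is taken to be 1-based inclusive already.
#' Typical use: intersecting a call set with open chromatin (ATAC-seq
#' peak) regions.
#'
#' @param variants A VCF record tibble.
#' @param regions A tibble with `chrom`, `start`, `end`, or a BED path.
#' @return The subset of `variants` falling inside the regions; its row
#'   count is the intersection count.
#' @export
snps_in_regions <- function(variants, regions) {
  if (is.character(regions)) regions <- read_bed(regions)
  samples <- vcf_samples(variants)
  hdr <- attr(variants, "header")
  if (nrow(regions) == 0 || nrow(variants) == 0) {
    return(new_vcf_records(variants[0, ], hdr, samples))
  }
  lvl <- unique(c(variants$chrom, regions$chrom))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(factor(variants$chrom, levels = lvl),
                           IRanges::IRanges(variants$pos, variants$pos)),
    GenomicRanges::GRanges(factor(regions$chrom, levels = lvl),
                           IRanges::IRanges(regions$start, regions$end)),
    select = "first")
  new_vcf_records(variants[!is.na(hits), ], hdr, samples)
}

#' Select the top and bottom score tails of a variant score table
#'
#' Uses nearest-rank selection: with n entries and tail fraction f, the
#' k = ceiling(f * n) highest-scoring and k lowest-scoring entries are
#' selected and their union returned. Ties at either cut are broken by
#' `site_id` order so the selection is deterministic; for tiny tables the
#' two tails may overlap (a site is returned once).
#'
#' @param scores Tibble with `site_id` and finite numeric `score`.
#' @param tail_fraction Fraction per tail, in (0, 0.5); default 0.05 (the
#'   top and bottom five percent).
#' @return The selected rows with an extra `tail` column (`"low"`,
#'   `"high"`, or `"both"`), ordered by score.
#' @export
percentile_tails <- function(scores, tail_fraction = 0.05) {
  if (nrow(scores) == 0) stop("score table is empty", call. = FALSE)
  if (!is.finite(tail_fraction) || tail_fraction <= 0 ||
      tail_fraction >= 0.5) {
    stop("`tail_fraction` must lie in (0, 0.5)", call. = FALSE)
  }
  if (any(!is.finite(scores$score))) {
    stop("scores must be finite", call. = FALSE)
  }
  n <- nrow(scores)
  k <- ceiling(tail_fraction * n)
  lo_idx <- order(scores$score, scores$site_id)[seq_len(k)]
  hi_idx <- order(-scores$score, scores$site_id)[seq_len(k)]
  idx <- union(lo_idx, hi_idx)
  out <- scores[idx, ]
  out$tail <- dplyr::case_when(
    idx %in% lo_idx & idx %in% hi_idx ~ "both",
    idx %in% lo_idx ~ "low",
    TRUE ~ "high"
  )
  out[order(out$score, out$site_id), ]
}

#' Read a two-column site score table
#'
#' @param path TSV with columns `site_id` and `score` (no header needed;
#'   a `site_id<TAB>score` header line is tolerated).
#' @return Tibble with `site_id` (character) and `score` (numeric).
#' @export
read_score_table <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("site_id", "score"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab$score[1])))) {
    tab <- tab[-1, ]
  }
  tibble::tibble(site_id = tab$site_id, score = as.numeric(tab$score))
}
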