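#' Read a per-genome presence map from BED
#'
#' Presence intervals are consumed as BED (0-based half-open) and converted
#' to the package's 1-based inclusive convention: a BED line
#' `chrom 4 5` becomes the single base `[5, 5]`.
#'
#' @param path BED file path (first three columns used).
#' @param genome_id Identifier attached to every interval.
#' @return A tibble with `genome_id`, `chrom`, `start`, `end`.
#' @export
read_presence_bed <- function(path, genome_id) {
  bed <- read_bed(path)
  tibble::tibble(genome_id = genome_id, chrom = bed$chrom,
                 start = bed$start, end = bed$end)
}

#' Read BED intervals as 1-based inclusive ranges
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) plus a
#'   `name` column when a 4th BED column is present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 3)) {
    stop("BED line with fewer than 3 columns in ", path, call. = FALSE)
  }
  mat <- t(vapply(fields, function(f) f[1:3], character(3)))
  out <- tibble::tibble(chrom = mat[, 1],
                        start = as.numeric(mat[, 2]) + 1,
                        end = as.numeric(mat[, 3]))
  if (all(lengths(fields) >= 4)) {
    out$name <- vapply(fields, function(f) f[4], character(1))
  }
  out
}

#' Write 1-based inclusive intervals as BED
#'
#' Extra columns beyond `chrom`, `start`, `end` are written after the
#' coordinates in the order given.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  cols <- c(list(intervals$chrom, fmt(intervals$start - 1),
                 fmt(intervals$end)),
            lapply(extra, function(e) as.character(intervals[[e]])))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

maps_to_grl <- function(maps, frame) {
  validate_genome_index(frame)
  unknown <- setdiff(unique(maps$chrom), frame$chrom)
  if (length(unknown) > 0) {
    stop("presence map references chromosome '", unknown[1],
         "' absent from the coordinate frame", call. = FALSE)
  }
  seqlen <- stats::setNames(frame$length, frame$chrom)
  lapply(split(maps, maps$genome_id), function(m) {
    gr <- GenomicRanges::GRanges(
      seqnames = factor(m$chrom, levels = frame$chrom),
      ranges = IRanges::IRanges(m$start, m$end),
      seqlengths = seqlen)
    GenomicRanges::reduce(gr)
  })
}

#' Classify pan-genome regions by occupancy across a genome panel
#'
#' Partitions the coordinate frame at every presence-interval breakpoint
#' and labels each fragment by how many of the N panel genomes cover it:
#' `core` when all N do, `dispensable` when 2..N-1 do, `specific` when
#' exactly one does. Uncovered bases (occupancy 0) are not labeled.
#' Adjacent fragments with equal occupancy (hence equal label) are merged.
#' Labels do not depend on the order in which the maps are supplied.
#'
#' @param maps Tibble of presence intervals with columns `genome_id`,
#'   `chrom`, `start`, `end` (1-based inclusive, disjoint per genome), for
#'   N >= 2 genomes on a shared coordinate frame.
#' @param frame A genome index defining the frame.
#' @return A tibble of class `pangenome_regions` with `chrom`, `start`,
#'   `end`, `occupancy`, `label`.
#' @export
classify_regions <- function(maps, frame) {
  grl <- maps_to_grl(maps, frame)
  n_genomes <- length(grl)
  if (n_genomes < 2) {
    stop("region classification needs presence maps for >= 2 genomes",
         call. = FALSE)
  }
  cov <- Reduce(`+`, lapply(grl, GenomicRanges::coverage))
  out <- purrr::map(frame$chrom, function(chrom) {
    r <- cov[[chrom]]
    runs <- tibble::tibble(
      chrom = chrom,
      start = cumsum(c(1, S4Vectors::runLength(r)))[seq_along(
        S4Vectors::runLength(r))],
      occupancy = as.integer(S4Vectors::runValue(r)),
      len = as.numeric(S4Vectors::runLength(r))
    )
    runs$end <- runs$start + runs$len - 1
    runs[runs$occupancy > 0, c("chrom", "start", "end", "occupancy")]
  })
  out <- dplyr::bind_rows(out)
  out$label <- dplyr::case_when(
    out$occupancy == n_genomes ~ "core",
    out$occupancy == 1 ~ "specific",
    TRUE ~ "dispensable"
  )
  class(out) <- c("pangenome_regions", class(tibble::tibble()))
  attr(out, "n_genomes") <- n_genomes
  out
}

#' Regions absent from a focal genome but present elsewhere
#'
#' Returns the fragments of the frame that the focal genome's presence map
#' does not cover while at least one other panel genome does.
#'
#' @inheritParams classify_regions
#' @param focal The `genome_id` whose absent regions are wanted; must be
#'   one of the genomes in `maps`.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
absent_regions <- function(maps, frame, focal) {
  grl <- maps_to_grl(maps, frame)
  if (!focal %in% names(grl)) {
    stop("unknown focal genome '", focal, "'", call. = FALSE)
  }
  others <- GenomicRanges::reduce(do.call(
    c, unname(lapply(grl[setdiff(names(grl), focal)], identity))))
  absent <- GenomicRanges::setdiff(others, grl[[focal]])
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(absent)),
    start = as.numeric(GenomicRanges::start(absent)),
    end = as.numeric(GenomicRanges::end(absent))
  )
}

#' Classify homologous gene groups by panel occupancy
#'
#' A group is `core` when a homolog is present in every panel genome,
#' `private` when present in exactly one, and `dispensable` otherwise.
#'
#' @param groups Long-format membership tibble with columns `group_id` and
#'   `genome_id` (one row per genome containing a homolog of the group).
#' @param panel Character vector of the N panel genome ids.
#' @return Tibble with `group_id`, `n_members`, `label`.
#' @export
classify_gene_groups <- function(groups, panel) {
  outside <- setdiff(unique(groups$genome_id), panel)
  if (length(outside) > 0) {
    stop("group member '", outside[1], "' is outside the declared panel",
         call. = FALSE)
  }
  n <- length(panel)
  out <- dplyr::summarise(dplyr::group_by(groups, .data$group_id),
                          n_members = dplyr::n_distinct(.data$genome_id),
                          .groups = "drop")
  out$label <- dplyr::case_when(
    out$n_members == n ~ "core",
    out$n_members == 1 ~ "private",
    TRUE ~ "dispensable"
  )
  out
}

#' Gene groups absent from one focal genome only
#'
#' Reports the groups present in exactly N-1 panel genomes with the focal
#' genome the missing one.
#'
#' @inheritParams classify_gene_groups
#' @param focal The focal `genome_id`.
#' @return Tibble of the focal-absent groups (`group_id`, `n_members`).
#' @export
gene_groups_absent_in <- function(groups, panel, focal) {
  if (!focal %in% panel) {
    stop("unknown focal genome '", focal, "'", call. = FALSE)
  }
  counts <- classify_gene_groups(groups, panel)
  has_focal <- unique(groups$group_id[groups$genome_id == focal])
  counts[counts$n_members == length(panel) - 1 &
           !counts$group_id %in% has_focal, c("group_id", "n_members")]
}

#' Count SNPs per pan-genome region class
#'
#' Each variant is assigned to the unique labeled fragment whose inclusive
#' range contains its position; variants outside every fragment are
#' counted as `unclassified`.
#'
#' @param variants A VCF record tibble.
#' @param regions Labeled fragments from [classify_regions()] (columns
#'   `chrom`, `start`, `end`, `label`).
#' @return Tibble with `label` and `n_snps`, one row per class present.
#' @export
count_snps_by_class <- function(variants, regions) {
  if (nrow(variants) == 0) {
    return(tibble::tibble(label = character(0), n_snps = numeric(0)))
  }
  lvl <- unique(c(regions$chrom, variants$chrom))
  snp_gr <- GenomicRanges::GRanges(factor(variants$chrom, levels = lvl),
                                   IRanges::IRanges(variants$pos,
                                                    variants$pos))
  reg_gr <- GenomicRanges::GRanges(factor(regions$chrom, levels = lvl),
                                   IRanges::IRanges(regions$start,
                                                    regions$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, reg_gr, select = "first")
  label <- ifelse(is.na(hits), "unclassified", regions$label[hits])
  dplyr::count(tibble::tibble(label = label), .data$label, name = "n_snps")
}

#' Plot per-class base totals of classified regions
#'
#' @param object A `pangenome_regions` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pangenome_regions <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$label),
    bases = sum(.data$end - .data$start + 1), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$bases,
                                   fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "bases",
                  title = "Pan-genome region classes") +
    ggplot2::theme_minimal()
}
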