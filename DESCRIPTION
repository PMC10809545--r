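Package: chunkcall
Title: Scatter-Gather Genome Chunking, Variant Hard Filtering and
    Pan-Genome SNP Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a reference genome into disjoint intervals
    ("chunks") for parallel joint genotyping, using a split-table
    algorithm that derives an optimal chunk length from the largest
    chromosome and a core budget. Generates per-chunk job manifests for
    pluggable external callers, and gathers per-chunk multi-sample VCFs
    back into a genome-wide call set with strict ordering and boundary
    guarantees. Also implements the downstream analyses commonly run on
    such call sets: GATK-style SNP hard filtering (QUAL, QD, MQ,
    MQRankSum, ReadPosRankSum, DP), pan-genome classification of regions
    and gene groups into core, dispensable, genome-specific and
    genome-absent classes, minor allele frequency, accession-support
    validation, intersection of SNPs with open chromatin regions, and
    percentile-tail selection of variant effect scores. Ships a seeded
    synthetic-data generator so every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    parallel,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
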