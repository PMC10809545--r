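# shared in-code fixtures: tiny VCF record tibbles and on-disk files

fixture_vcf_tibble <- function(chrom, pos, ref = "A", alt = "G",
                               qual = 50, info = NA_character_,
                               gt = NULL) {
  n <- length(pos)
  rec <- tibble::tibble(
    chrom = rep_len(chrom, n), pos = pos,
    id = NA_character_,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n), filter = NA_character_,
    info = rep_len(info, n)
  )
  if (!is.null(gt)) {
    rec$format <- "GT"
    for (s in names(gt)) rec[[s]] <- rep_len(gt[[s]], n)
  }
  rec
}

fixture_header <- function(frame) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%s>", frame$chrom,
            format(frame$length, scientific = FALSE, trim = TRUE)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
}

write_fixture_vcf <- function(rec, frame, path = tempfile(fileext = ".vcf")) {
  samples <- setdiff(names(rec), c("chrom", "pos", "id", "ref", "alt",
                                   "qual", "filter", "info", "format"))
  attr(rec, "header") <- fixture_header(frame)
  attr(rec, "samples") <- samples
  write_vcf(rec, path)
  path
}

# record-stream view of a VCF tibble: drops the header/sample attributes so
# two streams compare on their records alone
vcf_records <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "header") <- NULL
  attr(x, "samples") <- NULL
  x
}

# brute-force per-base occupancy oracle used by the pan-genome tests
perbase_occupancy <- function(maps, frame) {
  out <- lapply(seq_len(nrow(frame)), function(ci) {
    occ <- integer(frame$length[ci])
    for (g in unique(maps$genome_id)) {
      m <- maps[maps$genome_id == g & maps$chrom == frame$chrom[ci], ]
      covered <- logical(frame$length[ci])
      for (i in seq_len(nrow(m))) covered[m$start[i]:m$end[i]] <- TRUE
      occ <- occ + covered
    }
    occ
  })
  names(out) <- frame$chrom
  out
}
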