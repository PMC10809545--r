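test_that("make_manifest renders one command per chunk with interval and output", {
  cst <- build_cst(genome_index("Chr01", 30), chunk_length = 10)
  outdir <- withr::local_tempdir()
  man <- make_manifest(cst, "caller -L {interval} -I {inputs} -O {output}",
                       c("a.g.vcf", "b.g.vcf"), outdir)
  expect_equal(nrow(man), 3)
  expect_equal(man$interval, c("Chr01:1-10", "Chr01:11-20", "Chr01:21-30"))
  for (i in 1:3) {
    expect_true(grepl(man$interval[i], man$command[i], fixed = TRUE))
    expect_true(grepl(man$output[i], man$command[i], fixed = TRUE))
    expect_true(grepl("a.g.vcf b.g.vcf", man$command[i], fixed = TRUE))
  }
  expect_false(anyDuplicated(man$output) > 0)

  expect_error(make_manifest(cst, "caller -I {inputs} -O {output}",
                             "a.vcf", outdir), "\\{interval\\}")
  expect_error(make_manifest(cst, "caller {interval} {inputs} {output}",
                             character(0), outdir), "empty")
})

test_that("manifest serializes to TSV plus shell script and runs locally", {
  cst <- build_cst(genome_index("Chr01", 20), chunk_length = 10)
  outdir <- withr::local_tempdir()
  man <- make_manifest(cst, "echo {interval} {inputs} > {output}",
                       "in.vcf", outdir)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sh <- withr::local_tempfile(fileext = ".sh")
  write_manifest(man, tsv, sh)
  expect_equal(readLines(sh)[1], "#!/bin/sh")
  expect_true(file.exists(tsv))
  run_manifest(man)
  expect_true(all(file.exists(man$output)))
  expect_match(readLines(man$output[2]), "Chr01:11-20 in.vcf")
})

test_that("reference joint genotyping takes the in-interval site union with missing calls", {
  frame <- genome_index("Chr01", 100)
  f1 <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", c(5, 11), gt = list(SA = "0/1")), frame)
  f2 <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", 9, gt = list(SB = "1/1")), frame)
  jg <- reference_joint_genotype(c(f1, f2),
                                 tibble::tibble(chrom = "Chr01", start = 1,
                                                end = 10))
  # union inside [1,10]: pos 5 (SA only) and 9 (SB only); 11 excluded
  expect_equal(jg$pos, c(5, 9))
  expect_equal(jg$SA, c("0/1", "./."))
  expect_equal(jg$SB, c("./.", "1/1"))

  # a shared site yields one record with both genotypes called
  f3 <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", 5, gt = list(SB = "1/1")), frame)
  shared <- reference_joint_genotype(c(f1, f3),
                                     tibble::tibble(chrom = "Chr01",
                                                    start = 1, end = 10))
  expect_equal(shared$pos, 5)
  expect_equal(c(shared$SA, shared$SB), c("0/1", "1/1"))

  expect_error(
    reference_joint_genotype(c(f1, f2),
                             tibble::tibble(chrom = "ChrZ", start = 1,
                                            end = 10)),
    "coordinate frame")
})

test_that("joint site count equals the union of in-interval per-sample site sets", {
  withr::local_seed(11)
  frame <- genome_index("Chr01", 500)
  files <- vapply(1:4, function(i) {
    pos <- sort(sample.int(500, 40))
    write_fixture_vcf(
      fixture_vcf_tibble("Chr01", pos,
                         gt = setNames(list("0/1"), paste0("S", i))),
      frame)
  }, character(1))
  interval <- tibble::tibble(chrom = "Chr01", start = 101, end = 350)
  jg <- reference_joint_genotype(files, interval)
  union_oracle <- length(unique(unlist(lapply(files, function(f) {
    v <- read_vcf(f)
    v$pos[v$pos >= 101 & v$pos <= 350]
  }))))
  expect_equal(nrow(jg), union_oracle)
  expect_false(is.unsorted(jg$pos))
})

test_that("split then gather reproduces a 1000-record multi-sample stream exactly", {
  withr::local_seed(2024)
  frame <- genome_index(c("Chr01", "Chr02", "Chr03"),
                        c(40000, 30000, 20000))
  recs <- dplyr::bind_rows(lapply(seq_len(nrow(frame)), function(i) {
    n <- c(450, 330, 220)[i]
    fixture_vcf_tibble(frame$chrom[i], sort(sample.int(frame$length[i], n)),
                       ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                       gt = list(S1 = "0/1", S2 = "0/0", S3 = "1/1"))
  }))
  expect_equal(nrow(recs), 1000)
  src <- write_fixture_vcf(recs, frame)

  for (cl in c(1500, 7777, 50000)) {
    cst <- build_cst(frame, chunk_length = cl)
    outdir <- withr::local_tempdir()
    chunks <- split_vcf_by_cst(src, cst, outdir)
    expect_equal(sum(chunks$n_records), 1000)
    gat <- gather_chunk_vcfs(cst, chunks$path)
    orig <- read_vcf(src)
    expect_equal(vcf_records(gat), vcf_records(orig))
  }
})

test_that("split honors the inclusive-end convention and emits header-only empty chunks", {
  frame <- genome_index("Chr01", 10)
  cst <- build_cst(frame, chunk_length = 5)
  rec <- fixture_vcf_tibble("Chr01", c(3, 5), gt = list(S1 = "0/1"))
  outdir <- withr::local_tempdir()
  chunks <- split_vcf_by_cst(write_fixture_vcf(rec, frame), cst, outdir)
  # pos 5 == chunk end belongs to the first chunk; second chunk is empty
  expect_equal(chunks$n_records, c(2, 0))
  empty <- read_vcf(chunks$path[2])
  expect_equal(nrow(empty), 0)
  expect_equal(vcf_samples(empty), "S1")

  stray <- fixture_vcf_tibble("ChrZ", 1, gt = list(S1 = "0/1"))
  expect_error(
    split_vcf_by_cst(write_fixture_vcf(stray, genome_index("ChrZ", 10)),
                     cst, outdir),
    "ChrZ")
})

test_that("gather rejects boundary violations, sample mismatches and silent duplicates", {
  frame <- genome_index("Chr01", 4554834)
  cst <- build_cst(frame, chunk_length = 2277417)

  # record at 2277418 placed in the file for chunk [1, 2277417]
  bad <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", 2277418, gt = list(S1 = "0/1")), frame)
  ok <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", 3000000, gt = list(S1 = "0/1")), frame)
  expect_error(gather_chunk_vcfs(cst, c(bad, ok)),
               "2277418.*outside its interval")

  other_sample <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", 3000000, gt = list(S2 = "0/1")), frame)
  first <- write_fixture_vcf(
    fixture_vcf_tibble("Chr01", 100, gt = list(S1 = "0/1")), frame)
  expect_error(gather_chunk_vcfs(cst, c(first, other_sample)),
               "sample columns")

  # duplicated (chrom, pos, ref, alt) across chunks: error unless dedupe
  dup_cst <- build_cst(genome_index("Chr01", 10), chunk_length = 10)
  a <- write_fixture_vcf(fixture_vcf_tibble("Chr01", c(2, 2),
                                            gt = list(S1 = "0/1")),
                         genome_index("Chr01", 10))
  expect_error(gather_chunk_vcfs(dup_cst, a), "duplicate record")
  dd <- gather_chunk_vcfs(dup_cst, a, dedupe_boundaries = TRUE)
  expect_equal(nrow(dd), 1)
})

test_that("gathered output is sorted genome-wide with a provenance header line", {
  frame <- genome_index(c("Chr02", "Chr01"), c(20, 20))  # frame order != alphabetical
  cst <- build_cst(frame, chunk_length = 10)
  rec <- dplyr::bind_rows(
    fixture_vcf_tibble("Chr02", c(4, 15), gt = list(S1 = "0/1")),
    fixture_vcf_tibble("Chr01", c(7, 12), gt = list(S1 = "1/1")))
  outdir <- withr::local_tempdir()
  chunks <- split_vcf_by_cst(write_fixture_vcf(rec, frame), cst, outdir)
  out_path <- withr::local_tempfile(fileext = ".vcf")
  gat <- gather_chunk_vcfs(cst, chunks$path, out_path = out_path)
  expect_equal(gat$chrom, c("Chr02", "Chr02", "Chr01", "Chr01"))
  expect_equal(gat$pos, c(4, 15, 7, 12))
  expect_true(any(grepl("^##source=chunkcall gather", attr(gat, "header"))))
  expect_true(any(grepl("^##source=chunkcall gather",
                        readLines(out_path))))
})
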