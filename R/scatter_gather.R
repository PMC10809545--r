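#' Render a per-chunk job manifest for an external joint-genotyping command
#'
#' Produces one shell command per split-table chunk by filling a command
#' template. The template must contain the placeholders `{interval}`
#' (replaced by the 1-based inclusive `chrom:start-end` string),
#' `{inputs}` (space-separated input file paths) and `{output}` (a unique,
#' deterministic per-chunk output path under `outdir`, encoding the
#' chromosome and chunk number).
#'
#' @param cst A `cst` tibble from [build_cst()] or [read_cst()].
#' @param command_template Template string with `{interval}`, `{inputs}`
#'   and `{output}` placeholders.
#' @param input_paths Non-empty character vector of per-sample input files.
#' @param outdir Directory for per-chunk outputs (created if missing).
#' @return A tibble of class `job_manifest` with columns `chrom`,
#'   `chunk_no`, `start`, `end`, `interval`, `output`, `command`, one row
#'   per chunk in CST order.
#' @export
make_manifest <- function(cst, command_template, input_paths, outdir) {
  validate_cst(cst)
  for (ph in c("{interval}", "{inputs}", "{output}")) {
    if (!grepl(ph, command_template, fixed = TRUE)) {
      stop("command template lacks the ", ph, " placeholder", call. = FALSE)
    }
  }
  if (length(input_paths) == 0) {
    stop("`input_paths` must not be empty", call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  interval <- sprintf("%s:%s-%s", cst$chrom, fmt(cst$start), fmt(cst$end))
  output <- file.path(outdir,
                      sprintf("%s_%04d.vcf", cst$chrom, cst$chunk_no))
  inputs <- paste(input_paths, collapse = " ")
  command <- vapply(seq_len(nrow(cst)), function(i) {
    cmd <- gsub("{interval}", interval[i], command_template, fixed = TRUE)
    cmd <- gsub("{inputs}", inputs, cmd, fixed = TRUE)
    gsub("{output}", output[i], cmd, fixed = TRUE)
  }, character(1))
  out <- tibble::tibble(
    chrom = cst$chrom, chunk_no = cst$chunk_no, start = cst$start,
    end = cst$end, interval = interval, output = output, command = command
  )
  class(out) <- c("job_manifest", class(tibble::tibble()))
  out
}

#' Serialize a job manifest
#'
#' Writes the manifest as a TSV and, optionally, as a runnable shell
#' script (one command per line under `#!/bin/sh`).
#'
#' @param manifest A `job_manifest` tibble.
#' @param tsv_path Path for the TSV rendering.
#' @param script_path Optional path for the shell-script rendering.
#' @return `tsv_path`, invisibly.
#' @export
write_manifest <- function(manifest, tsv_path, script_path = NULL) {
  readr::write_tsv(tibble::as_tibble(manifest), tsv_path)
  if (!is.null(script_path)) {
    writeLines(c("#!/bin/sh", "set -e", manifest$command), script_path)
    Sys.chmod(script_path, "755")
  }
  invisible(tsv_path)
}

#' Run a job manifest locally
#'
#' Executes each manifest command with the shell, sequentially or with a
#' bounded worker pool. Per-chunk outputs are complete files before any
#' gather step should run. No cluster-scheduler submission is generated.
#'
#' @param manifest A `job_manifest` tibble.
#' @param jobs Number of concurrent workers (default 1 = sequential).
#' @return Integer vector of exit statuses (invisibly); errors if any
#'   command fails.
#' @export
run_manifest <- function(manifest, jobs = 1) {
  run_one <- function(cmd) system(cmd)
  status <- if (jobs > 1) {
    unlist(parallel::mclapply(manifest$command, run_one, mc.cores = jobs))
  } else {
    vapply(manifest$command, run_one, integer(1), USE.NAMES = FALSE)
  }
  if (any(status != 0)) {
    stop("manifest command failed (exit ", max(status), "): ",
         manifest$command[which(status != 0)[1]], call. = FALSE)
  }
  invisible(status)
}

#' Reference per-interval joint genotyper
#'
#' A deliberately simple combine-and-genotype stand-in used to exercise the
#' scatter/gather machinery without an external caller. For one chunk
#' interval it takes the union of the per-sample sites (matched on
#' chromosome, position, REF and ALT) whose position falls inside
#' `[start, end]`, and emits one multi-sample record per site with the
#' sample's genotype where present and `./.` where the sample has no record.
#' gVCF reference-block semantics are not modeled: every input record is an
#' explicit per-site call.
#'
#' @param sample_files Character vector of per-sample VCF paths; column
#'   order in the output follows this order.
#' @param interval A one-row data frame (e.g. a CST row) with `chrom`,
#'   `start`, `end`.
#' @return A multi-sample VCF record tibble sorted by position.
#' @export
reference_joint_genotype <- function(sample_files, interval) {
  if (length(sample_files) == 0) {
    stop("`sample_files` must not be empty", call. = FALSE)
  }
  per_sample <- purrr::map(sample_files, read_vcf)
  contigs <- dplyr::bind_rows(purrr::map(per_sample, vcf_contigs))
  if (nrow(contigs) > 0 && !interval$chrom %in% contigs$chrom) {
    stop("interval chromosome '", interval$chrom,
         "' is not declared in any input's coordinate frame", call. = FALSE)
  }
  sample_names <- purrr::imap_chr(per_sample, function(v, i) {
    s <- vcf_samples(v)
    if (length(s) >= 1) s[1] else paste0("sample", i)
  })
  if (anyDuplicated(sample_names)) {
    sample_names <- make.unique(sample_names, sep = "_")
  }
  in_window <- purrr::map(per_sample, function(v) {
    dplyr::filter(v, .data$chrom == interval$chrom,
                  .data$pos >= interval$start, .data$pos <= interval$end)
  })
  sites <- dplyr::distinct(
    dplyr::bind_rows(purrr::map(in_window, function(v) {
      v[, c("chrom", "pos", "id", "ref", "alt", "qual", "info")]
    })),
    .data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE
  )
  sites <- dplyr::arrange(sites, .data$pos, .data$ref, .data$alt)
  sites$filter <- NA_character_
  sites$format <- "GT"
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  site_key <- key(sites)
  for (i in seq_along(in_window)) {
    v <- in_window[[i]]
    gt <- rep("./.", nrow(sites))
    if (nrow(v) > 0) {
      scol <- vcf_samples(v)
      raw <- if (length(scol) >= 1) v[[scol[1]]] else rep("0/1", nrow(v))
      # keep the GT subfield only; the reference combiner carries no depths
      raw <- sub(":.*$", "", raw)
      m <- match(key(v), site_key)
      gt[m[!is.na(m)]] <- raw[!is.na(m)]
    }
    sites[[sample_names[i]]] <- gt
  }
  sites <- sites[, c("chrom", "pos", "id", "ref", "alt", "qual", "filter",
                     "info", "format", sample_names)]
  hdr <- attr(per_sample[[1]], "header")
  hdr <- hdr[!grepl("^##(FORMAT|INFO)=", hdr)]
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  new_vcf_records(sites, header = hdr, samples = sample_names)
}

#' Split a multi-sample VCF into per-chunk files
#'
#' The inverse of [gather_chunk_vcfs()]: each record lands in the unique
#' CST chunk whose 1-based inclusive range contains its position (a
#' position equal to a chunk's end belongs to that chunk). Chunks with no
#' records yield header-only files; no record is lost or duplicated.
#'
#' @param vcf A VCF record tibble or a path to a VCF file.
#' @param cst A `cst` tibble.
#' @param outdir Output directory (created if missing).
#' @return A tibble with `chrom`, `chunk_no`, `path`, `n_records`, one row
#'   per chunk in CST order.
#' @export
split_vcf_by_cst <- function(vcf, cst, outdir) {
  validate_cst(cst)
  if (is.character(vcf)) vcf <- read_vcf(vcf)
  unknown <- setdiff(unique(vcf$chrom), unique(cst$chrom))
  if (length(unknown) > 0) {
    stop("record on chromosome '", unknown[1],
         "' which is absent from the CST", call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hdr <- vcf_header_or_default(vcf)
  samples <- vcf_samples(vcf)
  out <- purrr::pmap(cst[, c("chrom", "chunk_no", "start", "end")],
    function(chrom, chunk_no, start, end) {
      rows <- vcf[vcf$chrom == chrom & vcf$pos >= start & vcf$pos <= end, ]
      path <- file.path(outdir, sprintf("%s_%04d.vcf", chrom, chunk_no))
      write_vcf(new_vcf_records(rows, hdr, samples), path)
      tibble::tibble(chrom = chrom, chunk_no = chunk_no, path = path,
                     n_records = nrow(rows))
    })
  dplyr::bind_rows(out)
}

#' Gather per-chunk VCFs into a genome-wide call set
#'
#' Assembles one multi-sample VCF per chunk (in CST order) into a single
#' genome-wide record stream, enforcing the scatter contract: every record
#' must lie inside its declared chunk, all files must carry identical
#' sample columns, and — because the chunks are disjoint — no two chunks may
#' contain the same (chrom, pos, ref, alt) record. Output is sorted by the
#' CST's chromosome order, then position. The header is taken from the
#' first chunk plus one provenance line.
#'
#' @param cst A `cst` tibble.
#' @param chunk_files Character vector of per-chunk VCF paths, one per CST
#'   row, in CST order.
#' @param dedupe_boundaries If `TRUE`, duplicated records across chunks are
#'   collapsed first-wins instead of raising an error. Off by default so
#'   that upstream interval bugs surface.
#' @param out_path Optional path; when given the gathered VCF is also
#'   written there.
#' @return The genome-wide VCF record tibble.
#' @export
gather_chunk_vcfs <- function(cst, chunk_files, dedupe_boundaries = FALSE,
                              out_path = NULL) {
  validate_cst(cst)
  if (length(chunk_files) != nrow(cst)) {
    stop("expected ", nrow(cst), " chunk files (one per CST row), got ",
         length(chunk_files), call. = FALSE)
  }
  chunks <- purrr::map(chunk_files, read_vcf)
  ref_samples <- vcf_samples(chunks[[1]])
  for (i in seq_along(chunks)) {
    v <- chunks[[i]]
    if (!identical(vcf_samples(v), ref_samples)) {
      stop("sample columns of chunk ", cst$chrom[i], ":", cst$chunk_no[i],
           " differ from the first chunk", call. = FALSE)
    }
    bad <- which(v$chrom != cst$chrom[i] | v$pos < cst$start[i] |
                   v$pos > cst$end[i])
    if (length(bad) > 0) {
      stop("chunk ", cst$chrom[i], ":", cst$chunk_no[i], " [",
           cst$start[i], "-", cst$end[i], "] contains a record at ",
           v$chrom[bad[1]], ":", format(v$pos[bad[1]], scientific = FALSE),
           " outside its interval", call. = FALSE)
    }
  }
  all_rec <- dplyr::bind_rows(purrr::map(chunks, tibble::as_tibble))
  if (nrow(all_rec) > 0) {
    k <- paste(all_rec$chrom, all_rec$pos, all_rec$ref, all_rec$alt)
    if (anyDuplicated(k)) {
      if (dedupe_boundaries) {
        all_rec <- all_rec[!duplicated(k), ]
      } else {
        stop("duplicate record across chunks at ",
             k[duplicated(k)][1],
             "; disjoint intervals should never produce duplicates ",
             "(set `dedupe_boundaries = TRUE` for foreign inputs)",
             call. = FALSE)
      }
    }
    chrom_order <- unique(cst$chrom)
    all_rec <- all_rec[order(match(all_rec$chrom, chrom_order),
                             all_rec$pos), ]
  }
  hdr <- c(attr(chunks[[1]], "header"),
           sprintf("##source=chunkcall gather of %d chunk files", nrow(cst)))
  out <- new_vcf_records(all_rec, header = hdr, samples = ref_samples)
  if (!is.null(out_path)) write_vcf(out, out_path)
  out
}
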