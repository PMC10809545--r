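#' @keywords internal
#' One named pseudo-random stream per generator: a single user seed is
#' combined with a fixed per-generator offset, so adding a generator never
#' perturbs the draws of an existing one. Offsets keep the derived seed
#' within 32-bit integer range.
#' @noRd
local_stream <- function(seed, stream, env = parent.frame()) {
  offsets <- c(genome = 101L, cohort = 211L, presence = 307L,
               manifest = 401L)
  withr::local_seed((as.integer(seed) %% 1000000L) * 1009L +
                      offsets[[stream]], .local_envir = env)
}

#' Simulate a genome index
#'
#' Draws `n_chrom` chromosome lengths uniformly in `[min_len, max_len]`
#' with names `Chr01`, `Chr02`, ... Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (>= 1).
#' @param min_len,max_len Length bounds in bp (1 <= min_len <= max_len).
#' @param path Optional path; when given the index is also written as a
#'   two-column `.fai`-style file.
#' @return A genome index tibble.
#' @export
synth_genome_index <- function(seed, n_chrom = 3, min_len = 5e4,
                               max_len = 1e5, path = NULL) {
  if (n_chrom < 1) stop("`n_chrom` must be >= 1", call. = FALSE)
  if (min_len < 1 || min_len > max_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  local_stream(seed, "genome")
  idx <- genome_index(
    sprintf("Chr%02d", seq_len(n_chrom)),
    floor(stats::runif(n_chrom, min_len, max_len + 1))
  )
  if (!is.null(path)) write_genome_index(idx, path)
  idx
}

#' Default annotation model for simulated cohorts
#'
#' Distributions for the six filterable annotations, chosen so that
#' roughly 10–30% of sites fail each condition of the default hard filter
#' and both branches of every condition are exercised:
#' QUAL ~ 20 + Exponential(mean 50) (so P(QUAL < 30) = 1 - e^-0.2 ~ 18%),
#' QD ~ Normal(5, 2.5) (~12% below 2), MQ ~ Normal(30, 10) (~16% below
#' 20), both rank sums ~ Normal(-1.5, 1.5) (~16% below -3), and
#' DP ~ Poisson(7) (P(DP < 5) = ppois(4, 7) ~ 17%).
#'
#' @return Named list of distribution parameters.
#' @export
annotation_defaults <- function() {
  list(qual_shift = 20, qual_mean = 50,
       qd_mean = 5, qd_sd = 2.5,
       mq_mean = 30, mq_sd = 10,
       rank_sum_mean = -1.5, rank_sum_sd = 1.5,
       dp_mean = 7)
}

#' Simulate a resequencing cohort with per-sample variant files
#'
#' Emulates the per-sample stage of a joint-genotyping workflow: SNP sites
#' are drawn uniformly along each chromosome at `snp_rate` per bp, each
#' site receives the six filterable annotations from the annotation model,
#' and each sample observes each site independently with probability
#' `obs_prob` (an observing sample is a het or hom-alt carrier; a
#' non-observing sample has no record in its file and so becomes a missing
#' genotype after joint genotyping). One VCF per sample is written under
#' `outdir`, and the planted truth — every site with its annotations, its
#' expected hard-filter verdict under the default thresholds, per-sample
#' genotypes and its carrier count — is returned alongside.
#'
#' @param seed Integer seed.
#' @param frame A genome index tibble.
#' @param n_samples Number of samples (>= 1).
#' @param snp_rate Per-bp probability of a site, in (0, 0.01].
#' @param outdir Directory for the per-sample VCFs.
#' @param obs_prob Per-sample, per-site observation probability.
#' @param model Annotation model, see [annotation_defaults()].
#' @return A list with `sample_files` (named character vector), `truth`
#'   (per-site tibble incl. `expected_pass` and genotype columns) and
#'   `frame`.
#' @export
synth_cohort <- function(seed, frame, n_samples, snp_rate = 1e-3,
                         outdir = tempfile("cohort"), obs_prob = 0.8,
                         model = annotation_defaults()) {
  validate_genome_index(frame)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  if (snp_rate < 0 || snp_rate > 0.01) {
    stop("`snp_rate` must lie in [0, 0.01]", call. = FALSE)
  }
  local_stream(seed, "cohort")
  bases <- c("A", "C", "G", "T")
  sites <- purrr::map2(frame$chrom, frame$length, function(chrom, len) {
    n <- stats::rbinom(1, len, snp_rate)
    if (n == 0) {
      return(tibble::tibble(chrom = character(0), pos = numeric(0)))
    }
    tibble::tibble(chrom = chrom, pos = sort(sample.int(len, n)))
  })
  truth <- dplyr::bind_rows(sites)
  n <- nrow(truth)
  samples <- sprintf("S%03d", seq_len(n_samples))
  if (n > 0) {
    truth$ref <- sample(bases, n, replace = TRUE)
    truth$alt <- vapply(truth$ref, function(r) {
      sample(setdiff(bases, r), 1)
    }, character(1), USE.NAMES = FALSE)
    truth$qual <- round(model$qual_shift +
                          stats::rexp(n, 1 / model$qual_mean), 2)
    truth$qd <- round(stats::rnorm(n, model$qd_mean, model$qd_sd), 2)
    truth$mq <- round(stats::rnorm(n, model$mq_mean, model$mq_sd), 2)
    truth$mq_rank_sum <- round(stats::rnorm(n, model$rank_sum_mean,
                                            model$rank_sum_sd), 3)
    truth$read_pos_rank_sum <- round(stats::rnorm(n, model$rank_sum_mean,
                                                  model$rank_sum_sd), 3)
    truth$dp <- stats::rpois(n, model$dp_mean)
    verdict <- hard_filter(truth[, c("qual", "qd", "mq", "mq_rank_sum",
                                     "read_pos_rank_sum", "dp")])
    truth$expected_pass <- verdict$passed
    truth$expected_reasons <- vapply(verdict$reasons, paste, character(1),
                                     collapse = ";")
    for (s in samples) {
      observed <- stats::runif(n) < obs_prob
      gt <- ifelse(stats::runif(n) < 0.5, "0/1", "1/1")
      truth[[s]] <- ifelse(observed, gt, NA_character_)
    }
    # a site no sample observes would vanish from the joint call set, so
    # re-assign each such site to one sample, round-robin
    unseen <- which(rowSums(!is.na(as.matrix(truth[, samples]))) == 0)
    for (i in unseen) {
      truth[[samples[(i - 1) %% n_samples + 1]]][i] <- "0/1"
    }
  } else {
    truth$ref <- character(0); truth$alt <- character(0)
    truth$qual <- numeric(0); truth$qd <- numeric(0)
    truth$mq <- numeric(0); truth$mq_rank_sum <- numeric(0)
    truth$read_pos_rank_sum <- numeric(0); truth$dp <- integer(0)
    truth$expected_pass <- logical(0)
    truth$expected_reasons <- character(0)
    for (s in samples) truth[[s]] <- character(0)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%s>", frame$chrom,
                      format(frame$length, scientific = FALSE,
                             trim = TRUE)),
              "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
              "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMSMappingQuality\">",
              "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQRankSum\">",
              "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"ReadPosRankSum\">",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  info <- if (n > 0) {
    sprintf("QD=%g;MQ=%g;MQRankSum=%g;ReadPosRankSum=%g;DP=%d",
            truth$qd, truth$mq, truth$mq_rank_sum, truth$read_pos_rank_sum,
            truth$dp)
  } else character(0)
  sample_files <- stats::setNames(
    file.path(outdir, paste0(samples, ".vcf")), samples)
  for (s in samples) {
    keep <- if (n > 0) !is.na(truth[[s]]) else logical(0)
    rec <- tibble::tibble(
      chrom = truth$chrom[keep], pos = truth$pos[keep],
      id = NA_character_, ref = truth$ref[keep], alt = truth$alt[keep],
      qual = truth$qual[keep], filter = NA_character_, info = info[keep],
      format = "GT")
    rec[[s]] <- truth[[s]][keep]
    write_vcf(new_vcf_records(rec, header, s), sample_files[[s]])
  }
  list(sample_files = sample_files, truth = truth, frame = frame)
}

#' Simulate panel presence maps with planted class fractions
#'
#' Lays out, along the whole frame, contiguous blocks whose true classes
#' are exactly the targets: a `core` block covered by all N genomes, a
#' `dispensable` block covered by 2..N-1 genomes (the occupancy cycles
#' through that range block-by-block and the covering genomes rotate, so
#' no genome ordering is privileged), a `specific` block covered by
#' exactly one genome (rotating), and an uncovered remainder. Per-class
#' base totals are exact by construction, making the layout its own
#' oracle for the region classifier.
#'
#' @param seed Integer seed (controls rotation phases only; totals are
#'   exact regardless).
#' @param frame A genome index tibble.
#' @param n_genomes Panel size N (>= 2; >= 3 when a dispensable fraction
#'   is requested).
#' @param fractions Named numeric `c(core=, dispensable=, specific=)`,
#'   each >= 0, summing to <= 1.
#' @return A list with `maps` (presence tibble: `genome_id`, `chrom`,
#'   `start`, `end`), `truth` (tibble `label`, `bases`) and `frame`.
#' @export
synth_presence_maps <- function(seed, frame, n_genomes,
                                fractions = c(core = 0.6,
                                              dispensable = 0.25,
                                              specific = 0.1)) {
  validate_genome_index(frame)
  if (n_genomes < 2) {
    stop("presence-map simulation needs >= 2 genomes", call. = FALSE)
  }
  fr <- fractions[c("core", "dispensable", "specific")]
  if (anyNA(fr) || any(fr < 0) || sum(fr) > 1 + 1e-9) {
    stop("`fractions` must be named core/dispensable/specific, each >= 0, ",
         "summing to <= 1", call. = FALSE)
  }
  if (fr[["dispensable"]] > 0 && n_genomes < 3) {
    stop("a dispensable fraction needs >= 3 genomes (occupancy 2..N-1 ",
         "is empty for N = 2)", call. = FALSE)
  }
  local_stream(seed, "presence")
  total <- sum(frame$length)
  n_bases <- floor(fr * total)
  genomes <- sprintf("G%02d", seq_len(n_genomes))

  # walk the frame linearly, cutting blocks of the requested class sizes;
  # blocks are capped at 10 kb so classes interleave across chromosomes
  frag_list <- list()
  remaining <- n_bases
  classes <- c("core", "dispensable", "specific", "none")
  class_i <- 1L
  disp_occ <- 2L
  rot <- sample.int(n_genomes, 1)
  block_cap <- 1e4
  for (ci in seq_len(nrow(frame))) {
    chrom <- frame$chrom[ci]
    at <- 1
    len <- frame$length[ci]
    while (at <= len) {
      while (class_i <= 3 && remaining[[classes[class_i]]] <= 0) {
        class_i <- class_i + 1L
      }
      cls <- classes[class_i]
      take <- min(block_cap, len - at + 1,
                  if (cls == "none") len - at + 1
                  else remaining[[cls]])
      if (cls != "none") {
        occ <- switch(cls,
                      core = n_genomes,
                      specific = 1L,
                      dispensable = {
                        o <- disp_occ
                        disp_occ <- if (disp_occ >= n_genomes - 1) 2L
                                    else disp_occ + 1L
                        o
                      })
        covering <- genomes[((rot + seq_len(occ) - 2) %% n_genomes) + 1]
        rot <- (rot %% n_genomes) + 1L
        frag_list[[length(frag_list) + 1]] <- tibble::tibble(
          genome_id = covering, chrom = chrom, start = at,
          end = at + take - 1)
        remaining[[cls]] <- remaining[[cls]] - take
      }
      at <- at + take
    }
    # restart class rotation per chromosome so early chromosomes don't
    # monopolise one class
    class_i <- 1L
  }
  maps <- dplyr::bind_rows(frag_list)
  truth <- tibble::tibble(label = c("core", "dispensable", "specific"),
                          bases = as.numeric(n_bases))
  list(maps = maps, truth = truth, frame = frame)
}

#' Build a structural-variant validation manifest
#'
#' One row per (sampled SV, query genome) pair, so the row count is
#' `(n_insertions + n_deletions) * n_queries` — e.g. sampling 50
#' insertions and 50 deletions against 15 query genomes yields 1500
#' entries.
#'
#' @param n_insertions,n_deletions Numbers of sampled SVs (>= 0).
#' @param n_queries Number of query genomes (>= 0).
#' @return A tibble with `sv_id`, `sv_type`, `query_genome`.
#' @export
synth_validation_manifest <- function(n_insertions, n_deletions,
                                      n_queries) {
  if (any(c(n_insertions, n_deletions, n_queries) < 0)) {
    stop("all arguments must be >= 0", call. = FALSE)
  }
  svs <- tibble::tibble(
    sv_id = c(sprintf("INS%03d", seq_len(n_insertions)),
              sprintf("DEL%03d", seq_len(n_deletions))),
    sv_type = c(rep("insertion", n_insertions),
                rep("deletion", n_deletions)))
  if (nrow(svs) == 0 || n_queries == 0) {
    return(tibble::tibble(sv_id = character(0), sv_type = character(0),
                          query_genome = character(0)))
  }
  tidyr::crossing(svs, query_genome = sprintf("Q%02d", seq_len(n_queries)))
}
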