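---
title: "Chunked joint genotyping and pan-genome SNP analysis with chunkcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked joint genotyping and pan-genome SNP analysis with chunkcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunkcall)
library(dplyr)
```

## The problem

Joint genotyping of large resequencing cohorts (thousands of accessions
against one or more reference genomes) is dominated by a serial merge step:
combining per-sample gVCFs into one multi-sample call set. The standard way
out is interval scatter/gather — partition the genome into disjoint
intervals, run the combine/genotype step per interval in parallel, and
concatenate the per-interval call sets. chunkcall implements the interval
arithmetic and the bookkeeping around that pattern, plus the analyses that
are typically run on the resulting call set: hard filtering, pan-genome
region classification, and population-level SNP summaries. The heavy
per-interval calling itself is delegated to any external command (GATK's
`CombineGVCFs`/`GenotypeGVCFs` being the canonical choice) through a
rendered job manifest; chunkcall never re-implements caller numerics.

## The chromosome split table

The split table (CST) is a 4-column table `(ChrName, Chunk_no, Start, End)`
of 1-based inclusive intervals that partition every chromosome exactly. The
chunk length is derived from the *largest* chromosome and a core budget
`max_parts` in three steps:

1. take the largest chromosome length $L$;
2. find the largest $n \le$ `max_parts` with $L \bmod n = 0$ — the
   "fairest" divisor, giving $n$ equal chunks;
3. apply the chunk length $L/n$ uniformly to every chromosome, so the last
   chunk of each shorter chromosome simply truncates at the chromosome end.

```{r}
idx <- genome_index("Chr01", 11387085)
build_cst(idx, chunk_length = 2277417)
```

Two edge rules are deliberate and documented rather than emergent:

* **Prime lengths.** When no divisor other than 1 exists within the budget
  (a prime $L$), the full budget `max_parts` is used and the final chunk of
  that chromosome absorbs the remainder. The alternative (falling back to a
  single chunk) would forfeit all parallelism exactly when the genome is
  largest.
* **Ties in chromosome length** are broken by index order: the first
  maximal chromosome anchors the calculation.

Coordinates are 1-based inclusive throughout; chunk $k$ spans
$[(k-1)\,c + 1,\ \min(kc, L)]$. A user-supplied fixed `chunk_length`
bypasses the divisor search entirely, which is how chunk-size sweeps are
run. `validate_cst()` re-checks every invariant (numbering, contiguity,
uniform length with a short final chunk) whenever a table is read from
disk, so a corrupted CST fails loudly before any job is launched.

## Scatter and gather

`make_manifest()` renders one shell command per chunk from a template with
`{interval}`, `{inputs}` and `{output}` placeholders; `run_manifest()`
executes them locally (sequentially or with a bounded worker pool), and
`gather_chunk_vcfs()` assembles the per-chunk VCFs. Gather enforces the
scatter contract rather than trusting it:

* every record must lie inside its declared chunk (violations report the
  chunk and position);
* all chunk files must carry identical sample columns;
* duplicate `(chrom, pos, ref, alt)` records across chunks are an **error**
  by default — disjoint intervals can never produce them, so a duplicate
  means an upstream interval bug. An opt-in `dedupe_boundaries = TRUE`
  collapses them first-wins for foreign inputs.

Records are placed by POS alone; a deletion allele whose REF string spans a
chunk boundary belongs to the chunk containing its POS. Output order is the
genome index's chromosome order, then position — never lexicographic.

`reference_joint_genotype()` is a deliberately simple per-interval combiner
so the machinery is testable without an external caller: it takes the union
of per-sample sites (matched on chromosome, position, REF and ALT — allele
sets are not merged across samples) and fills `./.` where a sample has no
record. gVCF reference blocks are not modeled; a sample without an explicit
record at a site is *missing*, not homozygous reference. Both
simplifications are acceptable for plumbing tests and wrong for production
calling, which is precisely why the external-command seam exists.

## The SNP hard filter

SNP sites are selected (`select_snps()`: single-base REF and all ALT
alleles single bases; mixed SNP/indel sites are dropped whole, since
allele pruning would require genotype re-mapping) and then filtered by the
fixed disjunction

```
QUAL < 30.0 || QD < 2.0 || MQ < 20.0 || MQRankSum < -3.0 ||
ReadPosRankSum < -3.0 || DP < 5.0
```

evaluated with three precise semantics:

* comparisons are **strict** — a site with every annotation exactly at its
  cutoff passes;
* a condition can only fail when its annotation is **present**; missing
  annotations never fail a condition (the conventional treatment of absent
  annotations; `missing_fails = TRUE` inverts this for stricter pipelines);
* failed-condition codes are reported in a fixed order
  (`QUAL;QD;...`) in the FILTER column in flag mode, or failing records are
  dropped in pass-only mode.

These semantics make filtering *monotone* (raising any annotation can never
turn a pass into a fail) and *chunk-commutative* (filtering a gathered call
set equals gathering per-chunk-filtered files), both of which are asserted
as randomized properties in the test suite.

## Pan-genome region and gene-group classes

Given per-genome presence maps on a shared coordinate frame (consumed as
BED, converted internally to 1-based inclusive), `classify_regions()`
computes the per-base occupancy $c$ across the $N$ panel genomes and labels
maximal equal-occupancy runs:

| label | occupancy |
|---|---|
| core | $c = N$ |
| dispensable | $2 \le c \le N-1$ |
| specific | $c = 1$ |
| (unlabeled) | $c = 0$ |

Fragments are merged when occupancy (and hence label) agrees on adjacent
runs; the occupancy column is kept on every fragment, so two adjacent
dispensable runs with different occupancy remain separate rows rather than
losing their counts. `absent_regions()` gives the complementary view for a
focal genome: bases it lacks that at least one other genome covers.
`classify_gene_groups()` applies the same occupancy logic to homologous
gene groups (core / dispensable / private by membership count, plus the
"absent from exactly this focal genome" report), and
`count_snps_by_class()` assigns variants to the unique fragment containing
their position, counting anything outside every fragment as unclassified.
The interval arithmetic is done with GenomicRanges coverage/overlap
machinery; the test suite checks it base-for-base against a brute-force
per-base occupancy scan on frames up to 10 kb.

Presence maps are an input contract: how presence/absence was derived
(whole-genome alignment, SV calling) is upstream of this package, and
per-genome intervals must be pre-resolved to disjoint ranges.

## Population summaries

* `site_maf()` — allele frequencies over non-missing called alleles (two
  per complete diploid call; haploid and half-missing calls contribute the
  alleles they carry); the MAF is the second-largest frequency, 0 when
  monomorphic, `NA` when no call exists. Missing calls are excluded from
  the denominator — the standard convention.
* `accession_support()` / `support_validation()` — a site's support is the
  number of accessions carrying at least one non-reference allele
  (hom-alt counts once: support is per accession, not per allele); the
  validation summary reports how many sites reach a minimum support,
  3 by default.
* `allele_status_summary()` — for a gene absent from part of a population:
  per-category counts (gene-absent plus one category per allele label) and
  percentages of *all* accessions, rounded half-up to two decimals. With
  3021 accessions of which 2173 lack the gene, 668 carry one allele and 180
  the other, the percentages are 22.11% and 5.96%.
* `snps_in_regions()` — positional intersection with e.g. ATAC-seq open
  chromatin peaks; BED input is shifted from 0-based half-open to 1-based
  inclusive, so BED line `chr 4 5` contains exactly position 5.
* `percentile_tails()` — nearest-rank tail selection:
  $k = \lceil f n \rceil$ top plus $k$ bottom entries, union, ties at
  either cut broken by `site_id` for determinism. Nearest-rank with a
  ceiling was chosen over interpolated quantiles because the selection must
  be a set of whole records; for $n = 1$ the two tails coincide and the
  single entry is returned once.

## The synthetic-data generators

The generators exist so every stage is testable offline, and each plants a
truth it must be possible to recover exactly:

* `synth_genome_index()` — `Chr01..ChrNN` with uniform lengths; a dozen
  chromosomes of 20–45 Mb emulates a rice-scale frame, while tests default
  to tens of kb so suites run in seconds.
* `synth_cohort()` — sites drawn uniformly at a per-bp rate (default
  1 × 10⁻³, at the upper end of SNP density in diverse plant panels, so
  small frames still yield enough sites); annotations drawn from
  `annotation_defaults()`: QUAL ~ 20 + Exp(mean 50), QD ~ N(5, 2.5),
  MQ ~ N(30, 10), both rank sums ~ N(−1.5, 1.5), DP ~ Poisson(7). The
  parameters were calibrated once so each filter condition fails for
  roughly 10–30% of sites — enough to exercise both branches of every
  condition; a standard-normal rank sum, for comparison, would put only
  0.1% of sites below −3 and leave that branch essentially untested. The
  expected verdict of every site is recorded at generation time, and each
  sample observes each site with probability 0.8 (a site no sample observes
  is re-assigned round-robin, since it could never appear in a joint call
  set).
* `synth_presence_maps()` — block layouts whose per-class base totals
  equal the requested fractions exactly; dispensable occupancy cycles
  through 2..N−1 and covering genomes rotate, so no genome ordering is
  privileged. Infeasible requests (dispensable with N = 2, fractions
  summing past 1) are rejected rather than renormalized.
* `synth_validation_manifest()` — the (SV × query-genome) cross join used
  for validation bookkeeping, e.g. (50 + 50) × 15 = 1500 rows.

A single integer seed drives one named stream per generator (seed plus a
fixed per-generator offset), so adding a generator never perturbs the
fixtures of an existing one, and every generator is byte-reproducible.

What the simulations do *not* emulate: linkage and population structure,
reference-block gVCF semantics, indels and structural variants within the
cohort files, and annotation correlations (QD and DP are drawn
independently, which real callers do not produce). Passing tests therefore
demonstrate the correctness of the interval arithmetic, filter semantics
and summary statistics — not robustness to every pathology of real caller
output.

## Numerical and design choices

* All genomic coordinates are 1-based inclusive internally; BED is
  converted at the boundary in both directions.
* `optimal_divisor()` interprets "fairness" as exact divisibility — the
  largest divisor within the budget — with the ceil-based remainder
  fallback reserved for lengths with no usable divisor.
* Reading a CST infers the chunk length as the *maximum* chunk span (the
  first chromosome may itself be shorter than the chunk length).
* Percentages are rounded half away from zero at two decimals
  (`round_half_up()`); base R's round-half-even would report 22.10 where
  22.11 is expected.
* Record identity throughout gather/dedupe is the tuple
  `(chrom, pos, ref, alt)`.
* Test problem sizes: property suites use frames of 2–10 kb (hundreds of
  randomized cases), the split→gather identity uses 1000-record cohorts,
  and distribution checks use ~10,000 simulated sites with a 4-sigma
  binomial band.

## Limitations

* The reference combiner is a test fixture in spirit: production joint
  genotyping should go through the manifest to a real caller.
* Indel filtering, VQSR-style recalibration and genotype-level (FORMAT)
  filters are out of scope; the hard filter applies to SNP sites.
* The local executor offers no cluster-scheduler integration; manifests
  are plain TSV/shell renderings that any scheduler can consume.
* Variant effect scores are consumed as a table; computing them is a
  modeling problem outside this package.
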