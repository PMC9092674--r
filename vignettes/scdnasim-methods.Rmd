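---
title: "Simulating single-cell DNA sequencing data with full ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating single-cell DNA sequencing data with full ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why simulate single-cell DNA-seq?

Single-cell DNA sequencing (scDNA-seq) resolves the genomic heterogeneity of
a tumor cell by cell, but the callers that detect point variants and copy
number from such data are hard to benchmark: real datasets rarely come with
a known answer, and published truth sets are small. `scDNAsim` takes the
opposite route — it *constructs* a dataset together with its complete ground
truth. From one parameter object it produces, per cell, a table of genomic
aberrations (SNPs, SNVs, short indels, copy-number segments), a diploid
mutated genome in FASTA, and FASTQ reads whose binned depth is proportional
to copy number; alongside, it writes everything a benchmark needs: the
variant tables, the clean and noisy cells-by-bins copy-number matrices, the
subclone label of every cell, and the exact segment breakpoints.

All randomness descends from one master seed through name-keyed child
streams (one per simulator stage and cell), so a run is reproducible byte
for byte and adding cells never reshuffles the draws of earlier cells.

```{r, eval = FALSE}
library(scDNAsim)

fx <- run_fixture("sim", contig_len = 2e6, n_snps = 10000, seed = 1)
params <- sim_params(ref_path = fx[["ref"]], snp_db_path = fx[["db"]],
                     out_dir = "sim/run", cell_no = 10, seed = 1)
run_pipeline(params, mode = "snp")
verify_run("sim/run")
```

## The four simulators

**SNPs.** Known polymorphisms are drawn from a SNP database (a five-column
TSV; a synthetic generator is bundled, see below). A batch of cells is
modelled as a population with similar but slightly varied SNP landscapes: a
*shared core* of `round(shared_snp_frac * snp_no)` sites (default 80%) is
sampled once and appears in every cell, and each cell's remaining private
sites are drawn disjointly across cells from the leftover pool. The
disjoint construction makes the shared fraction a property of the batch that
holds *exactly*, not in expectation. Shared sites carry one batch-wide
genotype; whether a site is heterozygous is a Bernoulli draw with rate
`het_rate` (default 0.5). The genotype model is this package's addition —
read pileups at simulated SNP sites show both mixed-allele and all-alternate
patterns, which requires het- and hom-capable sites; setting `het_rate = 1`
forces all-HET if a simpler model is wanted.

**SNVs.** De novo substitutions at distinct positions sampled uniformly over
the non-N reference, independently per cell (no sharing rule; sharing is a
property of inherited polymorphisms, not of somatic noise in this model).
The alternative base is uniform over the three non-reference bases.

**Indels.** Insertions or deletions with equal probability, length uniform
on 4–10 bp, inserted bases i.i.d. uniform. Anchors are rejection-sampled so
that occupied spans, padded with a 10 bp buffer, are pairwise disjoint
within a cell (and disjoint from any supplied point-variant positions). The
buffer — the maximum indel length — is a package rule: it guarantees that
genome building is unambiguous and that every ground-truth record can be
verified independently in the built sequence. The deletion anchor is the
first deleted base (a length-5 deletion at `pos` removes `pos..pos+4`);
this differs from VCF's anchor-before convention and is documented in the
profile schema.

**CNV.** The genome is tiled into `bin_len`-wide bins (default 500 kb;
terminal bins may be shorter). Per chromosome, `seg_no - 1` interior bin
boundaries drawn without replacement partition the bins into `seg_no`
segments; a breakpoint's coordinate is the end of its upstream segment, so
interior breakpoints fall on `bin_len` multiples. Cells are split into
`round(normal_frac * cell_no)` normal cells (the first indices, for
reproducible labels) and `cluster_no` tumor subclones, each seeded with one
cell so none is empty. Every subclone gets a per-segment profile: neutral
(CN = 2) with probability `p_neutral` (default 0.5), else uniform over
`{0, 1} ∪ {3..max_cn}`; all-neutral and duplicate profiles are redrawn, so
subclones are genuine, distinct aberration patterns. `max_cn` defaults to 8,
a ceiling that keeps amplifications in the range scDNA-seq CNV callers
typically model. The noisy matrix perturbs each entry independently with
probability `noise_rate` by ±1 copy, clipped to `[0, max_cn]` with the
direction re-flipped if the clip would land back on the clean value — a
deliberately small-magnitude, integer-preserving noise model; the rate is
the parameter, the step model is the package's choice. With
`cluster_no = 0` the batch is entirely normal. When exact published
breakpoints are wanted instead of random draws,
`segments_from_breakpoints()` accepts an explicit list.

## From aberrations to sequence

**Diploid genomes.** Each cell's genome is two explicit haplotypes.
Homozygous variants edit both; heterozygous variants edit one haplotype
chosen by a fair coin (the *phase*). Substitutions are applied in place;
indels by piecewise reconstruction, with a monotone coordinate map kept per
haplotype (insertions shift downstream positions by +L; deleted positions
are undefined; positions past a deletion shift by −L). Phase is decided here
— not in the variant profiles — and written as a per-cell phase TSV next to
the haplotype FASTAs, because re-verifying a run from files alone needs it
to rebuild the coordinate maps.

Copy number is *not* materialized in the FASTA (no segment duplication):
it is realized at read-sampling time as depth. This keeps haplotype
coordinates stable, which is what makes exact point-variant verification
possible, while still producing the depth signal CNV callers consume.

**Reads.** For each bin with copy number `cn`, the template count is
Poisson with mean

```
lambda = coverage * bin_width / bases_per_template * cn / 2
```

(`bases_per_template` = `read_len` for SE, `2 * read_len` for PE), so a
CN = 2 bin attains the configured `coverage` and depth is exactly linear in
copy number — an 8-fold step at a CN 1→8 breakpoint. Templates pick a
haplotype 50/50 (total CN modulates depth; allelic imbalance is out of
scope), and a uniform start such that the template fits inside the
haplotype-mapped bin extent; templates never straddle bin boundaries, which
keeps per-bin counts exactly Poisson and breakpoint depth steps sharp.
Paired-end fragments draw their length from
`Normal(insert_mean, insert_sd)` truncated below at `2 * read_len`; mate 2
is the reverse complement of the fragment end. Sequencing error is a uniform
per-base substitution at `error_rate` (default 0.002); qualities are a
constant Phred `base_quality` (default 30, i.e. `?` in Phred+33). Read
names carry a truth tag `cell|hap|contig|start|mate` giving each read's
origin haplotype and 1-based start, so with `error_rate = 0` every read is
an exact substring (mate 2: reverse complement) of its source haplotype at
its tag position. The read model is deliberately protocol-agnostic: no
amplification bias, GC bias, allele dropout or chimera model — a uniform
Poisson sampler whose one guaranteed signal is depth ∝ CN.

**Verification.** The *generating-accuracy* of a dataset is the fraction of
ground-truth variants verifiably present in the built genomes: for each
record, the expected base (substitutions), inserted sequence (insertions)
or absent span plus intact junction (deletions) is checked at the
coordinate-mapped position on the haplotype(s) its genotype and phase imply.
`verify_run()` recomputes this from a run directory using only the written
files — profiles, phase tables and haplotype FASTAs — and reports per-class
averages; a fresh run verifies at 100% for every class, and the test suite
asserts exactly that.

## The synthetic reference and SNP database

`generate_synthetic_reference()` emits i.i.d. bases with a configurable GC
fraction (`P(G) = P(C) = gc/2`), no N bases, contigs named `sim1, sim2, …`.
`generate_synthetic_dbsnp()` samples distinct non-N positions uniformly,
sets `ref` from the genome and `alt` uniformly among the other three bases,
with sequential `rsS…`-prefixed identifiers marking records as synthetic.
These fixtures make the whole pipeline self-contained and are what the test
suite runs on.

What they do *not* emulate: real genomes have repeats, GC structure and N
gaps; real SNP databases have allele-frequency structure and clustering;
real scDNA-seq has amplification artifacts. Passing tests therefore
demonstrate the *internal correctness* of the simulator — exact sharing
fractions, exact breakpoints, 100% round-trip verification, depth
proportional to CN — not that downstream callers will behave on real data
exactly as they do on simulated data.

## Numerical and design choices

* **Seeding.** Child seeds are derived by hashing `(seed, stage, index)`
  into `[1, 2^31 - 2]` with a multiplicative string hash; each stage/cell
  runs in its own stream and the caller's RNG state is restored afterwards.
* **Rounding.** Normal-cell counts and the shared-SNP count use round half
  away from zero, so 40% of 100 cells is exactly 40 and 80% of 1000 SNPs is
  exactly 800.
* **Rejection budgets.** Indel placement allows 100 tries per indel (plus a
  constant) before failing; subclone profile draws allow 1000 tries to find
  a distinct, non-neutral vector. Both fail with explicit errors rather than
  silently degrading.
* **Degenerate inputs.** Zero-variant settings produce valid empty profiles;
  a `bin_len` wider than the genome yields one bin per contig; bins whose
  mapped extent cannot host a template are skipped with a warning; CN 0 bins
  emit no reads.
* **Manifest.** `manifest.json` records the parameter snapshot (minus the
  output directory), the seed, the package version and an md5 checksum per
  output file, and contains no wall-clock state — identical parameters and
  seed reproduce it byte for byte; timestamps live in `run.log`.
* **Problem sizes.** The shipped tests and the acceptance script run
  10-cell batches on a 2 Mb synthetic contig (1000 SNPs/SNVs and 100 indels
  per cell), 100 × 103 copy-number matrices on a chr22-sized contig, and
  coverage-5 depth-recovery checks on 100 kb bins — sizes chosen so a full
  check runs on a laptop in a couple of minutes while keeping every
  statistical band (3σ) meaningful.

## Limitations

No evolutionary relationship among subclones (profiles are drawn
independently, not on a phylogeny); no allele-specific copy number or
whole-genome doubling; no linkage or population allele frequencies among
SNPs; no amplification-protocol profile, allele dropout or GC bias in the
read model; FASTQ only (alignment is left to the consumer). These are
deliberate scope boundaries: the package's contract is exact,
machine-checkable ground truth for the signals it does simulate.
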