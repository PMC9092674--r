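# scDNAsim

Synthetic single-cell DNA sequencing (scDNA-seq) data with complete ground
truth, for benchmarking single-cell variant and copy-number callers.

Benchmarking scDNA-seq callers is limited by the scarcity of datasets with a
known answer. `scDNAsim` generates the dataset *and* its answer: from one
parameter object it simulates, per cell, genomic aberrations (SNPs, SNVs,
short indels, copy-number segments), a diploid mutated genome in FASTA, and
FASTQ reads whose binned depth tracks copy number — and writes every
simulated quantity as machine-readable ground truth: variant tables, clean
and noisy cells × bins copy-number matrices, subclone cell labels, and exact
segment breakpoints. A bundled synthetic reference-genome and SNP-database
generator makes everything runnable offline.

## The model in brief

* **SNPs** are drawn from a SNP database with an exact batch-shared core:
  `round(shared_snp_frac · snp_no)` sites (default 80 %) recur in every
  cell; private sites are disjoint across cells. Genotypes are HET with
  probability `het_rate`, shared sites sharing one batch-wide genotype.
* **SNVs** are uniform de novo substitutions, private per cell; **indels**
  are 4–10 bp insertions/deletions (uniform length, equal kinds) placed
  with a 10 bp non-overlap buffer.
* **CNV**: the genome is tiled into `bin_len` bins; each chromosome is cut
  into `seg_no` segments (`seg_no − 1` breakpoints on bin boundaries);
  cells split into `round(normal_frac · cell_no)` normals plus
  `cluster_no` non-empty subclones with distinct per-segment profiles over
  `{0,1} ∪ {3..max_cn}`; a noisy matrix perturbs entries by ±1 copy at rate
  `noise_rate`.
* **Genomes** are two explicit haplotypes (HET variants phased by fair
  coin); copy number is realized as read depth, not in the FASTA.
* **Reads**: per bin, `Poisson(coverage · bin_width / bases_per_template ·
  cn/2)` templates, SE or PE, uniform substitution errors, constant Phred
  quality, truth tags `cell|hap|contig|start|mate` in read names.
* **Verification**: the *generating-accuracy* — the fraction of
  ground-truth variants verifiably present in the built genomes — is
  recomputed from the written files by `verify_run()`; fresh runs verify at
  100 % for all three variant classes.

## Worked example

```r
library(scDNAsim)

td <- tempfile()
fx <- run_fixture(td, contig_len = 2e6, n_snps = 10000, seed = 1)

params <- sim_params(ref_path = fx[["ref"]], snp_db_path = fx[["db"]],
                     out_dir = file.path(td, "snp_run"),
                     cell_no = 10, snp_no = 1000, seed = 1)
run_pipeline(params, mode = "snp")
v <- verify_run(file.path(td, "snp_run"))
#> snp    average generating-accuracy: 100.0%

params$out_dir <- file.path(td, "cnv_run")
params$bin_len <- 100000L   # 20 bins on the 2 Mb fixture
res <- run_pipeline(params, mode = "cnv")
nrow(res$cnv$segments$breakpoints)
#> [1] 6
table(res$cnv$assignment$label)
#>
#> clone1 clone2 clone3 clone4 normal
#>      1      2      3      2      2
```

The SNP run writes per-cell profile TSVs, haplotype FASTA pairs with phase
tables, and FASTQ reads under `snp_run/`; `verify_run()` re-checks every
ground-truth variant against the written genomes and prints the per-class
average — 100.0 % here, meaning every simulated variant is present at its
mapped coordinate. The CNV run has the default `seg_no = 7` segments per
chromosome (hence 6 breakpoints) and `cluster_no = 4` subclones plus
`normal_frac = 0.2` normals, i.e. 5 subpopulations; `cnv_run/cnv/` holds the
clean and noisy matrices, cluster labels, breakpoints and segment BED.

A thin command-line wrapper covers the same pipeline
(`inst/scripts/scdnasim.R` with subcommands `fixture`, `snp`, `snv`,
`indel`, `cnv`, `verify`).

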