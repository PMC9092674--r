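Package: scDNAsim
Title: Synthetic Single-Cell DNA Sequencing Data with Full Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-cell DNA sequencing experiments end to end:
    per-cell genomic aberrations (SNPs drawn from a SNP database with a
    batch-shared core, de novo SNVs, short indels, and a cells-by-bins
    integer copy-number matrix with subclone structure, normal cells and
    noise), diploid mutated genomes in FASTA, and FASTQ reads whose per-bin
    depth is proportional to copy number. Every simulated quantity is
    emitted as machine-readable ground truth (variant tables, clean and
    noisy CNV matrices, subclone cell labels, segment breakpoints) so that
    single-cell variant and CNV callers can be benchmarked against a known
    answer. A synthetic reference-genome and SNP-database generator makes
    the whole pipeline self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
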