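# Shared in-memory fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# 200 kb single-contig synthetic genome used by most unit tests
test_genome <- function() {
  if (is.null(fixture_env$genome))
    fixture_env$genome <- generate_synthetic_reference(
      n_contigs = 1L, contig_len = 2e5, gc = 0.5, seed = 101L)
  fixture_env$genome
}

test_db <- function() {
  if (is.null(fixture_env$db))
    fixture_env$db <- generate_synthetic_dbsnp(test_genome(), 5000L,
                                               seed = 101L)
  fixture_env$db
}

test_params <- function(...) {
  p <- sim_params(cell_no = 3L, snp_no = 100L, snv_no = 50L, indel_no = 20L,
                  cluster_no = 1L, normal_frac = 0, seg_no = 3L,
                  bin_len = 20000L, coverage = 0.5, seed = 11L)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  validate_params(p)
}

# 2 Mb genome + SNP database for the batch-scale acceptance checks
acc_genome <- function() {
  if (is.null(fixture_env$acc_genome))
    fixture_env$acc_genome <- generate_synthetic_reference(
      n_contigs = 1L, contig_len = 2e6, gc = 0.5, seed = 1L)
  fixture_env$acc_genome
}

acc_db <- function() {
  if (is.null(fixture_env$acc_db))
    fixture_env$acc_db <- generate_synthetic_dbsnp(acc_genome(), 10000L,
                                                   seed = 1L)
  fixture_env$acc_db
}

# tiny hand-written genome for exact-coordinate tests
toy_genome <- function(seq = "ACGTACGTACGTACGTACGTACGTACGTACGT") {
  ref_genome(c(c1 = seq))
}

# independent base lookup used to cross-check generator output
base_at_test <- function(g, chrom, pos) {
  vapply(seq_along(pos),
         function(i) substr(g$seq[[chrom[i]]], pos[i], pos[i]), "")
}
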