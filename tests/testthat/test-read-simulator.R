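test_that("the per-bin Poisson mean is linear in copy number", {
  p <- test_params(coverage = 1, read_len = 100L, layout = "SE")
  expect_equal(expected_reads_per_bin(500000, 2L, p), 5000)
  expect_equal(expected_reads_per_bin(500000, 0L, p), 0)
  expect_equal(expected_reads_per_bin(500000, 8L, p) /
               expected_reads_per_bin(500000, 2L, p), 4)
  pe <- test_params(coverage = 1, read_len = 100L, layout = "PE")
  expect_equal(expected_reads_per_bin(500000, 2L, pe), 2500)
})

test_that("error-free reads are exact haplotype substrings at their truth tags", {
  g <- test_genome()
  p <- test_params(cell_no = 1L, coverage = 0.5, error_rate = 0)
  bins <- make_bins(g, p$bin_len)
  hap <- build_cell_genome(g, cell_id = "cell0")
  set.seed(1)
  batch <- simulate_cell_reads(hap, bins, NULL, p)
  expect_true(length(batch$seq) > 100L)
  expect_true(all(nchar(batch$seq) == p$read_len))
  tags <- strsplit(batch$name, "|", fixed = TRUE)
  for (i in sample.int(length(batch$seq), 50L)) {
    t <- tags[[i]]
    h <- sub("hap", "", t[2])
    st <- as.integer(t[4])
    expect_identical(batch$seq[i],
                     substring(hap$hap[[h]][[t[3]]], st,
                               st + p$read_len - 1L))
  }
})

test_that("total SE read count matches the summed Poisson mean within 3 sigma", {
  g <- test_genome()  # 200 kb
  p <- test_params(cell_no = 1L, coverage = 1, error_rate = 0)
  bins <- make_bins(g, p$bin_len)
  hap <- build_cell_genome(g, cell_id = "cell0")
  set.seed(2)
  batch <- simulate_cell_reads(hap, bins, NULL, p)
  lambda <- sum(vapply(seq_len(nrow(bins)), function(b)
    expected_reads_per_bin(bins[b, ], 2L, p), 1.0))
  expect_equal(lambda, 2000)
  expect_lt(abs(length(batch$seq) - lambda), 3 * sqrt(lambda))
})

test_that("read depth tracks copy number across a simulated CN 1 -> 8 breakpoint", {
  g <- test_genome()
  p <- test_params(cell_no = 1L, coverage = 5, error_rate = 0,
                   bin_len = 10000L)
  bins <- make_bins(g, p$bin_len)  # 20 bins
  cn_row <- c(rep(1L, 10L), rep(8L, 10L))
  hap <- build_cell_genome(g, cell_id = "cell0")
  set.seed(3)
  batch <- simulate_cell_reads(hap, bins, cn_row, p)
  counts <- bin_read_counts(batch, nrow(bins))
  up <- sum(counts[1:10]); down <- sum(counts[11:20])
  ratio <- down / up
  # delta-method sigma for a Poisson ratio
  sigma <- ratio * sqrt(1 / up + 1 / down)
  expect_lt(abs(ratio - 8), 3 * sigma)
})

test_that("the substitution-error rate is realized within 3 sigma", {
  g <- test_genome()
  p <- test_params(cell_no = 1L, coverage = 2, error_rate = 0.01)
  bins <- make_bins(g, p$bin_len)
  hap <- build_cell_genome(g, cell_id = "cell0")
  set.seed(4)
  batch <- simulate_cell_reads(hap, bins, NULL, p)
  n_bases <- sum(nchar(batch$seq))
  expect_gt(n_bases, 1e5)
  mism <- 0L
  for (i in seq_along(batch$seq)) {
    t <- strsplit(batch$name[i], "|", fixed = TRUE)[[1]]
    st <- as.integer(t[4])
    truth <- substring(hap$hap[[sub("hap", "", t[2])]][[t[3]]], st,
                       st + p$read_len - 1L)
    mism <- mism + sum(utf8ToInt(batch$seq[i]) != utf8ToInt(truth))
  }
  rate <- mism / n_bases
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n_bases))
})

test_that("paired-end batches are mate-consistent and FASTQ encoding is exact", {
  g <- test_genome()
  p <- test_params(cell_no = 1L, coverage = 0.5, error_rate = 0,
                   layout = "PE", base_quality = 30L)
  bins <- make_bins(g, p$bin_len)
  hap <- build_cell_genome(g, cell_id = "cell0")
  set.seed(5)
  batch <- simulate_cell_reads(hap, bins, NULL, p)
  expect_equal(length(batch$seq), length(batch$seq2))
  expect_true(all(nchar(batch$seq2) == p$read_len))
  # mate 2 reverse-complements the haplotype at its own tag position
  t2 <- strsplit(batch$name2[1], "|", fixed = TRUE)[[1]]
  st2 <- as.integer(t2[4])
  fwd <- substring(hap$hap[[sub("hap", "", t2[2])]][[t2[3]]], st2,
                   st2 + p$read_len - 1L)
  expect_identical(batch$seq2[1],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(fwd))))

  d <- withr::local_tempdir()
  paths <- write_fastq(batch, d)
  expect_length(paths, 2L)
  l1 <- readLines(paths[1])
  expect_equal(length(l1), 4L * length(batch$seq))
  expect_identical(l1[3], "+")
  expect_identical(l1[4], strrep("?", p$read_len))  # Phred+33 of Q30
  expect_identical(substr(l1[1], 1, 1), "@")

  # byte-identical regeneration under the same seed
  set.seed(5)
  batch2 <- simulate_cell_reads(hap, bins, NULL, p)
  d2 <- withr::local_tempdir()
  paths2 <- write_fastq(batch2, d2)
  expect_identical(readLines(paths2[1]), l1)
})

test_that("CN 0 bins are silent and short mapped extents are skipped with a warning", {
  g <- toy_genome(strrep("ACGT", 12500L))  # 50 kb
  p <- test_params(cell_no = 1L, coverage = 2, bin_len = 10000L,
                   error_rate = 0)
  bins <- make_bins(g, p$bin_len)
  hap <- build_cell_genome(g, cell_id = "cell0")
  set.seed(6)
  batch <- simulate_cell_reads(hap, bins, c(0L, 2L, 2L, 2L, 2L), p)
  counts <- bin_read_counts(batch, 5L)
  expect_equal(counts[1], 0L)
  expect_true(all(counts[-1] > 0L))

  # a 50 bp terminal bin cannot host a 100 bp read
  g2 <- toy_genome(strrep("ACGT", 2512L))  # 10048 bp
  p2 <- test_params(cell_no = 1L, coverage = 20, bin_len = 10000L)
  bins2 <- make_bins(g2, p2$bin_len)
  hap2 <- build_cell_genome(g2, cell_id = "cell0")
  set.seed(7)
  expect_warning(simulate_cell_reads(hap2, bins2, NULL, p2), "skipped")
})
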