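test_that("a heterozygous SNP lands on exactly one haplotype", {
  g <- toy_genome("AAAAAAAAAA")
  snp <- data.frame(chrom = "c1", pos = 5L, ref = "A", alt = "G",
                    genotype = "HET")
  set.seed(1)
  hap <- build_cell_genome(g, snps = snp)
  bases <- c(substr(hap$hap$A[["c1"]], 5, 5), substr(hap$hap$B[["c1"]], 5, 5))
  expect_setequal(bases, c("A", "G"))
  carrier <- hap$phase$hap[1]
  expect_true(carrier %in% c("A", "B"))
  expect_equal(bases[match(carrier, c("A", "B"))], "G")
})

test_that("homozygous edits hit both haplotypes and lengths are bookkept", {
  g <- toy_genome(strrep("ACGT", 20L))  # 80 bp
  del <- data.frame(chrom = "c1", pos = 21L, kind = "DEL", length = 5L,
                    seq = "", genotype = "HOM")
  ins <- data.frame(chrom = "c1", pos = 50L, kind = "INS", length = 7L,
                    seq = "TTTTTTT", genotype = "HOM")
  set.seed(2)
  hap <- build_cell_genome(g, indels = rbind(del, ins))
  for (h in c("A", "B"))
    expect_equal(nchar(hap$hap[[h]][["c1"]]), 80L - 5L + 7L)
  # inserted bases sit after the mapped anchor
  m <- map_ref_to_hap(hap$events$A$c1, 50L)
  expect_equal(substr(hap$hap$A[["c1"]], m + 1, m + 7), "TTTTTTT")
  # deleted span is unmapped, downstream positions shift by -5
  expect_true(all(is.na(map_ref_to_hap(hap$events$A$c1, 21:25))))
  expect_equal(map_ref_to_hap(hap$events$A$c1, 26L), 21L)
})

test_that("no variants reproduces the reference; positions outside variants match it", {
  g <- test_genome()
  hap0 <- build_cell_genome(g, cell_id = "c")
  expect_identical(hap0$hap$A, g$seq)
  expect_identical(hap0$hap$B, g$seq)

  p <- test_params(cell_no = 1L, snv_no = 200L, indel_no = 40L)
  snvs <- simulate_snv_profiles(p, g)$cell0
  indels <- simulate_indel_profiles(
    p, g, avoid = list(snvs[, c("chrom", "pos")]))$cell0
  set.seed(3)
  hap <- build_cell_genome(g, snvs = snvs, indels = indels)
  # length bookkeeping identity per haplotype
  for (h in c("A", "B")) {
    ev <- hap$events[[h]]$sim1
    delta <- sum(ev$length[ev$kind == "INS"]) -
      sum(ev$length[ev$kind == "DEL"])
    expect_equal(nchar(hap$hap[[h]][["sim1"]]), nchar(g$seq[["sim1"]]) + delta)
  }
  # sampled positions outside all variant intervals agree with the reference
  occupied <- sort(unique(c(snvs$pos,
                            unlist(Map(seq, indels$pos,
                                       indels$pos + indels$length)))))
  set.seed(4)
  spots <- setdiff(sample.int(nchar(g$seq[["sim1"]]), 500L), occupied)
  for (h in c("A", "B")) {
    m <- map_ref_to_hap(hap$events[[h]]$sim1, spots)
    expect_true(all(substring(hap$hap[[h]][["sim1"]], m, m) ==
                    substring(g$seq[["sim1"]], spots, spots)))
  }
})

test_that("freshly built cells verify at exactly 1.0 for all variant classes", {
  g <- test_genome()
  db <- test_db()
  p <- test_params(cell_no = 3L, snp_no = 80L, snv_no = 60L, indel_no = 25L)
  snps <- simulate_snp_profiles(p, db)
  snvs <- simulate_snv_profiles(p, g)
  indels <- simulate_indel_profiles(p, g)
  for (i in 1:3) {
    cid <- paste0("cell", i - 1L)
    set.seed(100 + i)
    hs <- build_cell_genome(g, snps = snps$cells[[cid]], cell_id = cid)
    expect_equal(verify_generating_accuracy(g, snps$cells[[cid]], hs, "snp"),
                 1.0)
    hv <- build_cell_genome(g, snvs = snvs[[cid]], cell_id = cid)
    expect_equal(verify_generating_accuracy(g, snvs[[cid]], hv, "snv"), 1.0)
    hi <- build_cell_genome(g, indels = indels[[cid]], cell_id = cid)
    expect_equal(verify_generating_accuracy(g, indels[[cid]], hi, "indel"),
                 1.0)
  }
})

test_that("an induced profile corruption is detected as 49/50", {
  g <- test_genome()
  p <- test_params(cell_no = 1L, snv_no = 50L)
  snvs <- simulate_snv_profiles(p, g)$cell0
  set.seed(5)
  hap <- build_cell_genome(g, snvs = snvs)
  flip <- snvs
  flip$alt[7] <- setdiff(c("A", "C", "G", "T"),
                         c(flip$alt[7], flip$ref[7]))[1]
  expect_equal(verify_generating_accuracy(g, flip, hap, "snv"), 49 / 50)
  # empty profile is vacuously perfect
  expect_equal(verify_generating_accuracy(g, snvs[0, ], hap, "snv"), 1.0)
})

test_that("variants outside the contig or overlapping are rejected", {
  g <- toy_genome("ACGTACGTAC")
  bad <- data.frame(chrom = "c1", pos = 99L, ref = "A", alt = "G",
                    genotype = "HOM")
  expect_error(build_cell_genome(g, snvs = bad), "out of contig range")
  over <- data.frame(chrom = "c1", pos = c(3L, 4L), kind = c("DEL", "DEL"),
                     length = c(4L, 4L), seq = "", genotype = "HOM")
  expect_error(build_cell_genome(g, indels = over), "overlapping")
})

test_that("haplotype FASTAs and phase tables are written per cell, reproducibly", {
  g <- test_genome()
  p <- test_params(cell_no = 2L, snv_no = 30L)
  snvs <- simulate_snv_profiles(p, g)
  d <- withr::local_tempdir()
  for (i in 1:2) {
    cid <- paste0("cell", i - 1L)
    set.seed(i)
    paths <- write_cell_fastas(build_cell_genome(g, snvs = snvs[[cid]],
                                                 cell_id = cid), d)
    expect_true(all(file.exists(paths)))
    expect_identical(names(read_fasta(paths[["hapA"]])$seq), "sim1")
  }
  expect_length(list.files(d, pattern = "fasta$"), 4L)
})
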