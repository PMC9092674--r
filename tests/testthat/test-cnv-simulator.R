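test_that("bins tile contigs exactly, including remainder and whole-chromosome cases", {
  b1 <- make_bins(c(c1 = 2000000L), 500000L)
  expect_equal(nrow(b1), 4L)
  expect_equal(b1$end[4], 2000000L)

  b2 <- make_bins(c(c1 = 2300000L), 500000L)
  expect_equal(nrow(b2), 5L)
  expect_equal(b2$end[5] - b2$start[5] + 1L, 300000L)

  # chr22-sized contig at the default bin width
  b3 <- make_bins(c(chr22 = 51304566L), 500000L)
  expect_equal(nrow(b3), ceiling(51304566 / 500000))  # 103
  expect_true(all(b3$start[-1] == b3$end[-nrow(b3)] + 1L))

  expect_equal(nrow(make_bins(c(c1 = 1000L), 5000L)), 1L)
})

test_that("seg_no segments always mean seg_no - 1 breakpoints, per chromosome", {
  bins <- make_bins(c(chr22 = 51304566L), 500000L)
  set.seed(1)
  for (sn in c(5L, 10L, 7L, 1L)) {
    segs <- draw_segments(bins, sn)
    expect_equal(nrow(segs$breakpoints), sn - 1L)
    expect_equal(nrow(segs$segments), sn)
  }
  # per chromosome on a two-contig genome
  bins2 <- make_bins(c(a = 5e6, b = 5e6), 500000L)
  segs2 <- draw_segments(bins2, 4L)
  expect_equal(nrow(segs2$breakpoints), 6L)
  expect_equal(table(segs2$segments$chrom), table(c(rep("a", 4), rep("b", 4))))
  # interior breakpoints are bin_len multiples
  expect_true(all(segs2$breakpoints$pos %% 500000L == 0L))

  expect_error(draw_segments(make_bins(c(c1 = 1e6), 500000L), 3L), "exceeds")
})

test_that("explicit breakpoint lists reproduce fixed segmentations", {
  bins <- make_bins(c(chr22 = 51304566L), 500000L)
  bp <- data.frame(chrom = "chr22",
                   pos = c(29500000L, 31500000L, 39000000L, 40500000L,
                           43000000L, 49500000L))
  segs <- segments_from_breakpoints(bins, bp)
  expect_equal(nrow(segs$segments), 7L)
  expect_identical(segs$breakpoints$pos, bp$pos)
  expect_equal(segs$segments$start[1], 1L)
  expect_equal(segs$segments$end[1], 29500000L)
  expect_error(segments_from_breakpoints(bins, data.frame(chrom = "chr22",
                                                          pos = 123L)),
               "not a bin boundary")
})

test_that("cluster assignment yields exact normal counts and non-empty clones", {
  set.seed(2)
  a <- assign_clusters(100L, 7L, 0.2)
  expect_equal(sum(a$label == "normal"), 20L)
  expect_setequal(unique(a$label), c("normal", paste0("clone", 1:7)))
  expect_true(all(table(a$label[a$label != "normal"]) >= 1L))
  expect_identical(a$label[1:20], rep("normal", 20L))

  b <- assign_clusters(100L, 4L, 0.2)
  expect_equal(length(unique(b$label)), 5L)

  c1 <- assign_clusters(10L, 1L, 0)
  expect_true(all(c1$label == "clone1"))
  c0 <- assign_clusters(10L, 0L, 0.9)
  expect_true(all(c0$label == "normal"))
})

test_that("subclone profiles avoid neutral-only and duplicate vectors", {
  bins <- make_bins(c(c1 = 5e6), 500000L)
  set.seed(3)
  segs <- draw_segments(bins, 7L)
  profs <- draw_clone_profiles(segs, 2L, max_cn = 8L)
  expect_equal(dim(profs), c(2L, 7L))
  expect_true(all(apply(profs, 1, function(r) any(r != 2L))))
  expect_false(all(profs[1, ] == profs[2, ]))

  # p_neutral = 0 never yields CN 2
  seg1 <- draw_segments(bins, 1L)
  draws <- replicate(200, draw_clone_profiles(seg1, 1L, 8L, p_neutral = 0)[1])
  expect_false(any(draws == 2L))
  expect_true(all(draws %in% c(0:1, 3:8)))

  # aberrant states are uniform over the 8-state alphabet
  set.seed(4)
  segs10 <- draw_segments(make_bins(c(c1 = 6e6), 500L), 5000L)
  big <- draw_clone_profiles(segs10, 2L, 8L, p_neutral = 0)
  tab <- table(factor(big, levels = c(0:1, 3:8)))
  n <- length(big)
  expect_true(all(abs(tab / n - 1/8) < 3 * sqrt((1/8) * (7/8) / n)))

  # tiny alphabet cannot host many distinct profiles
  expect_error(draw_clone_profiles(seg1, 9L, 3L, p_neutral = 0,
                                   max_tries = 10L), "distinct")
})

test_that("the clean matrix is block-constant: normals all 2, clones constant per segment", {
  bins <- make_bins(c(c1 = 5e6), 500000L)
  set.seed(5)
  segs <- draw_segments(bins, 4L)
  a <- assign_clusters(12L, 3L, 0.25)
  profs <- draw_clone_profiles(segs, 3L, 8L)
  m <- build_matrix(a, profs, segs, bins)
  expect_equal(dim(m$clean), c(12L, 10L))
  expect_true(all(m$clean[a$label == "normal", ] == 2L))
  for (cl in rownames(profs)) {
    rows <- which(a$label == cl)
    expect_true(all(apply(m$clean[rows, , drop = FALSE], 2,
                          function(col) length(unique(col)) == 1L)))
    for (k in seq_len(nrow(segs$segments))) {
      cols <- segs$segments$bin_from[k]:segs$segments$bin_to[k]
      expect_true(all(m$clean[rows, cols] == profs[cl, k]))
    }
  }
  # same-subpopulation rows identical, different subpopulations differ
  expect_false(all(m$clean[which(a$label == "clone1")[1], ] ==
                   m$clean[which(a$label == "clone2")[1], ]))
})

test_that("noise injection respects rate, step size and bounds", {
  bins <- make_bins(c(c1 = 5e6), 500000L)
  set.seed(6)
  segs <- draw_segments(bins, 3L)
  a <- assign_clusters(6L, 2L, 0)
  m <- build_matrix(a, draw_clone_profiles(segs, 2L, 8L), segs, bins)

  m0 <- inject_noise(m, 0, 8L)
  expect_identical(m0$noisy, m0$clean)

  a2 <- assign_clusters(10L, 0L, 0)
  m2 <- build_matrix(a2, matrix(integer(0), 0, 3), segs, bins)
  m2 <- inject_noise(m2, 1, 8L)
  expect_true(all(m2$noisy %in% c(1L, 3L)))
  expect_true(all(m2$noisy != m2$clean))

  mh <- inject_noise(m, 0.3, 8L)
  expect_true(all(abs(mh$noisy - mh$clean) <= 1L))
  expect_true(all(mh$noisy >= 0L & mh$noisy <= 8L))
  expect_identical(mh$clean, m$clean)
})

test_that("CNV ground-truth files are complete, exact and round-trippable", {
  bins <- make_bins(c(chr22 = 51304566L), 500000L)
  set.seed(7)
  segs <- draw_segments(bins, 7L)
  a <- assign_clusters(20L, 4L, 0.2)
  m <- build_matrix(a, draw_clone_profiles(segs, 4L, 8L), segs, bins)
  m <- inject_noise(m, 0.1, 8L)
  d <- withr::local_tempdir()
  paths <- write_cnv_outputs(m, d)

  bp <- read.table(paths[["breakpoints"]], header = TRUE, sep = "\t")
  expect_equal(nrow(bp), 6L)
  bed <- read.table(paths[["segments"]], sep = "\t")
  expect_equal(nrow(bed), 7L)
  # BED is 0-based half-open; breakpoints are upstream-segment ends
  expect_equal(bed$V2[1], 0L)
  expect_equal(bed$V3[-7], bp$pos)
  expect_equal(bed$V2[-1], bp$pos)
  expect_equal(bed$V3[7], 51304566L)

  expect_identical(read_cnv_matrix(paths[["clean"]]), m$clean)
  expect_identical(read_cnv_matrix(paths[["noisy"]]), m$noisy)

  cl <- read.csv(paths[["clusters"]])
  expect_equal(nrow(cl), 20L)
  expect_equal(sum(cl$label == "normal"), 4L)
})

test_that("a 60-bin segment starting at bin 1 ends at 29.5 Mb in BED and breakpoints", {
  bins <- make_bins(c(chr22 = 51304566L), 500000L)
  segs <- segments_from_breakpoints(bins,
                                    data.frame(chrom = "chr22",
                                               pos = 29500000L))
  expect_equal(segs$segments$bin_to[1], 59L)
  expect_equal(segs$segments$end[1], 29500000L)
  expect_equal(segs$breakpoints$pos, 29500000L)
})
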