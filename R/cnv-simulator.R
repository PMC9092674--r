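# CNV simulator: cells-by-bins integer copy-number matrix with subclone
# structure, normal cells, segment breakpoints and injected noise. This is
# the ground-truth core that single-cell CNV callers are benchmarked
# against.

#' Tile a genome into fixed-width bins
#'
#' Bins tile each contig exactly with no gaps or overlap; every bin is
#' `bin_len` wide except a possibly shorter terminal bin, so a contig has
#' `ceiling(length / bin_len)` bins. Coordinates are 1-based inclusive.
#'
#' @param genome a `ref_genome`, or a named vector of contig lengths.
#' @param bin_len bin width in bp.
#' @return a `bin_set` data.frame with columns chrom, start, end, label
#'   (`"chrom:start-end"`), in genome order.
#' @export
make_bins <- function(genome, bin_len) {
  stopifnot(bin_len >= 1)
  lens <- if (inherits(genome, "ref_genome")) contig_lengths(genome)
          else genome
  df <- if (bin_len <= sum(lens)) {
    tiles <- GenomicRanges::tileGenome(lens, tilewidth = as.integer(bin_len),
                                       cut.last.tile.in.chrom = TRUE)
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(tiles)),
      start = GenomicRanges::start(tiles),
      end = GenomicRanges::end(tiles),
      stringsAsFactors = FALSE)
  } else {
    # bins wider than the whole genome: one bin per contig
    data.frame(chrom = names(lens), start = 1L, end = as.integer(lens),
               stringsAsFactors = FALSE)
  }
  df$label <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  class(df) <- c("bin_set", "data.frame")
  df
}

#' Draw copy-number segments per chromosome
#'
#' For each contig, `seg_no - 1` interior bin boundaries are sampled
#' uniformly without replacement and sorted, partitioning the contig's bins
#' into `seg_no` segments. A breakpoint's genomic coordinate is the end of
#' the last bin of its upstream segment (1-based inclusive), i.e. a multiple
#' of `bin_len` for interior boundaries. Consumes the current RNG state; wrap
#' in `set.seed()` (or a pipeline stream) for reproducibility.
#'
#' @param bins a `bin_set`.
#' @param seg_no segments per chromosome (`seg_no <=` bins per contig).
#' @return a `segment_set`: list with `segments` (data.frame chrom,
#'   segment_id, bin_from, bin_to — global bin indices — start, end) and
#'   `breakpoints` (data.frame chrom, pos).
#' @export
draw_segments <- function(bins, seg_no) {
  stopifnot(seg_no >= 1)
  boundaries <- lapply(unique(bins$chrom), function(cn) {
    n_bins <- sum(bins$chrom == cn)
    if (seg_no > n_bins)
      stop(sprintf("seg_no=%d exceeds the %d bins of contig '%s'",
                   seg_no, n_bins, cn), call. = FALSE)
    if (seg_no == 1L) integer(0)
    else sort(sample.int(n_bins - 1L, seg_no - 1L))
  })
  names(boundaries) <- unique(bins$chrom)
  segments_from_boundaries(bins, boundaries)
}

#' Build segments from explicit breakpoints
#'
#' Alternative to [draw_segments()] when exact breakpoint coordinates are
#' wanted (e.g. to reproduce a published configuration). Each breakpoint
#' position must be the end coordinate of a non-terminal bin.
#'
#' @param bins a `bin_set`.
#' @param breakpoints data.frame with columns chrom, pos (1-based inclusive
#'   end of the upstream segment).
#' @return a `segment_set`.
#' @export
segments_from_breakpoints <- function(bins, breakpoints) {
  boundaries <- lapply(unique(bins$chrom), function(cn) {
    sel <- bins$chrom == cn
    ends <- bins$end[sel]
    bp <- sort(breakpoints$pos[breakpoints$chrom == cn])
    idx <- match(bp, ends)
    if (anyNA(idx))
      stop(sprintf("breakpoint %s:%d is not a bin boundary",
                   cn, bp[is.na(idx)][1]), call. = FALSE)
    if (any(idx >= sum(sel)))
      stop("a breakpoint may not sit at the contig end", call. = FALSE)
    idx
  })
  names(boundaries) <- unique(bins$chrom)
  segments_from_boundaries(bins, boundaries)
}

segments_from_boundaries <- function(bins, boundaries) {
  seg_rows <- list()
  bp_rows <- list()
  sid <- 0L
  for (cn in unique(bins$chrom)) {
    sel <- which(bins$chrom == cn)
    n_bins <- length(sel)
    bnd <- boundaries[[cn]]
    from <- c(1L, bnd + 1L)
    to <- c(bnd, n_bins)
    for (k in seq_along(from)) {
      sid <- sid + 1L
      seg_rows[[sid]] <- data.frame(
        chrom = cn, segment_id = paste0("seg", sid),
        bin_from = sel[from[k]], bin_to = sel[to[k]],
        start = bins$start[sel[from[k]]], end = bins$end[sel[to[k]]],
        stringsAsFactors = FALSE)
    }
    if (length(bnd) > 0L)
      bp_rows[[cn]] <- data.frame(chrom = cn, pos = bins$end[sel[bnd]],
                                  stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  breakpoints <- if (length(bp_rows) > 0L) {
    b <- do.call(rbind, bp_rows); rownames(b) <- NULL; b
  } else data.frame(chrom = character(0), pos = integer(0))
  structure(list(segments = segments, breakpoints = breakpoints),
            class = "segment_set")
}

#' Assign cells to normal/subclone labels
#'
#' Exactly `round(normal_frac * cell_no)` cells (half away from zero) — the
#' first cell indices, for reproducible labels — are `"normal"`. Each of the
#' `cluster_no` subclones is seeded with one tumor cell, then the remaining
#' tumor cells are assigned i.i.d. uniformly, so every subclone is non-empty.
#' With `cluster_no = 0` the whole batch is normal. Consumes the current RNG
#' state.
#'
#' @param cell_no number of cells.
#' @param cluster_no number of tumor subclones.
#' @param normal_frac fraction of normal cells.
#' @return data.frame with columns cell_id, label (`"normal"` or
#'   `"clone1"`..`"clone{cluster_no}"`).
#' @export
assign_clusters <- function(cell_no, cluster_no, normal_frac) {
  cell_ids <- paste0("cell", seq_len(cell_no) - 1L)
  if (cluster_no == 0L)
    return(data.frame(cell_id = cell_ids, label = rep("normal", cell_no),
                      stringsAsFactors = FALSE))
  n_normal <- as.integer(round_half_up(normal_frac * cell_no))
  n_tumor <- cell_no - n_normal
  if (n_tumor < cluster_no)
    stop(sprintf("infeasible clusters: %d tumor cells < %d clusters",
                 n_tumor, cluster_no), call. = FALSE)
  clones <- paste0("clone", seq_len(cluster_no))
  tumor_labels <- c(clones,
                    if (n_tumor > cluster_no)
                      sample(clones, n_tumor - cluster_no, replace = TRUE))
  data.frame(cell_id = cell_ids,
             label = c(rep("normal", n_normal), tumor_labels),
             stringsAsFactors = FALSE)
}

#' Draw per-subclone copy-number profiles
#'
#' For every subclone and segment: copy-neutral (CN = 2) with probability
#' `p_neutral`, otherwise an aberrant copy number uniform over
#' `{0, 1} U {3, ..., max_cn}`. Profiles that are all-neutral are redrawn
#' (every subclone carries at least one aberration) and duplicate profiles
#' across subclones are redrawn, so subclones are pairwise distinct. Consumes
#' the current RNG state.
#'
#' @param segments a `segment_set`.
#' @param cluster_no number of subclones.
#' @param max_cn copy-number ceiling.
#' @param p_neutral probability a segment is copy-neutral.
#' @param max_tries redraw budget per subclone.
#' @return integer matrix `cluster_no x n_segments` with rownames
#'   `clone1..`, colnames segment ids.
#' @export
draw_clone_profiles <- function(segments, cluster_no, max_cn,
                                p_neutral = 0.5, max_tries = 1000L) {
  n_seg <- nrow(segments$segments)
  aberrant <- c(0:1, 3:max_cn)
  profiles <- matrix(NA_integer_, nrow = cluster_no, ncol = n_seg,
                     dimnames = list(paste0("clone", seq_len(cluster_no)),
                                     segments$segments$segment_id))
  for (cl in seq_len(cluster_no)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      neutral <- stats::runif(n_seg) < p_neutral
      cn <- ifelse(neutral, 2L, sample(aberrant, n_seg, replace = TRUE))
      if (all(cn == 2L)) next
      if (cl > 1L &&
          any(apply(profiles[seq_len(cl - 1L), , drop = FALSE], 1L,
                    function(r) all(r == cn)))) next
      profiles[cl, ] <- as.integer(cn)
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not realize %d distinct subclone profiles (segment space too small)",
                   cluster_no), call. = FALSE)
  }
  profiles
}

#' Expand subclone profiles into the clean cells-by-bins CNV matrix
#'
#' Normal cells are 2 everywhere; a tumor cell's row is its subclone's
#' per-segment profile expanded across each segment's bins. Deterministic.
#'
#' @param assignment result of [assign_clusters()].
#' @param clone_profiles result of [draw_clone_profiles()].
#' @param segments a `segment_set`.
#' @param bins a `bin_set`.
#' @return a `cnv_matrix` object: list with `clean` (integer matrix, rownames
#'   cell ids, colnames bin labels), `noisy` (`NULL` until
#'   [inject_noise()]), `bins`, `segments`, `assignment`.
#' @export
build_matrix <- function(assignment, clone_profiles, segments, bins) {
  n_cells <- nrow(assignment)
  n_bins <- nrow(bins)
  seg <- segments$segments
  m <- matrix(2L, nrow = n_cells, ncol = n_bins,
              dimnames = list(assignment$cell_id, bins$label))
  for (cl in rownames(clone_profiles)) {
    rows <- which(assignment$label == cl)
    if (length(rows) == 0L) next
    row_cn <- integer(n_bins)
    for (k in seq_len(nrow(seg)))
      row_cn[seg$bin_from[k]:seg$bin_to[k]] <- clone_profiles[cl, k]
    m[rows, ] <- matrix(row_cn, nrow = length(rows), ncol = n_bins,
                        byrow = TRUE)
  }
  structure(list(clean = m, noisy = NULL, bins = bins, segments = segments,
                 assignment = assignment),
            class = "cnv_matrix")
}

#' Inject noise into a CNV matrix
#'
#' Each entry is independently perturbed with probability `noise_rate`; a
#' perturbed entry moves by +-1 copy with equal probability, clipped to
#' `[0, max_cn]` — a move that would leave the range is re-flipped to the
#' opposite direction, so a perturbed entry always differs from its clean
#' value. The clean matrix is left untouched. Consumes the current RNG state.
#'
#' @param mat a `cnv_matrix`.
#' @param noise_rate per-entry perturbation probability.
#' @param max_cn copy-number ceiling.
#' @return `mat` with its `noisy` field filled.
#' @export
inject_noise <- function(mat, noise_rate, max_cn) {
  clean <- mat$clean
  n <- length(clean)
  perturb <- stats::runif(n) < noise_rate
  delta <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  cand <- clean + delta
  flip <- cand < 0L | cand > max_cn
  cand[flip] <- clean[flip] - delta[flip]
  noisy <- clean
  noisy[perturb] <- cand[perturb]
  mat$noisy <- noisy
  mat
}

#' Write all CNV ground-truth files
#'
#' Emits, under `out_dir`:
#' * `cnv_matrix_clean.csv` / `cnv_matrix_noisy.csv` — rows = cells (first
#'   column `cell_id`), columns = bin labels `chrom:start-end`;
#' * `clusters.csv` — `cell_id,label`;
#' * `breakpoints.tsv` — `chrom<TAB>pos`, 1-based inclusive upstream-segment
#'   ends;
#' * `segments.bed` — 0-based half-open `chrom start end segment_id`.
#'
#' @param mat a `cnv_matrix` with noise injected.
#' @param out_dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_cnv_outputs <- function(mat, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(mat$noisy)) stop("inject_noise() must run before writing")
  write_mat <- function(m, path) {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    clean = write_mat(mat$clean, file.path(out_dir, "cnv_matrix_clean.csv")),
    noisy = write_mat(mat$noisy, file.path(out_dir, "cnv_matrix_noisy.csv")))
  cl_path <- file.path(out_dir, "clusters.csv")
  utils::write.table(mat$assignment, cl_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  bp_path <- file.path(out_dir, "breakpoints.tsv")
  write_tsv(mat$segments$breakpoints, bp_path)
  seg <- mat$segments$segments
  bed <- data.frame(chrom = seg$chrom, start = seg$start - 1L, end = seg$end,
                    name = seg$segment_id, stringsAsFactors = FALSE)
  bed_path <- file.path(out_dir, "segments.bed")
  con <- file(bed_path, "w")
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(paths, clusters = cl_path, breakpoints = bp_path,
              segments = bed_path))
}

#' Read a CNV matrix CSV written by [write_cnv_outputs()]
#'
#' @param path CSV path.
#' @return integer matrix with cell-id rownames and bin-label colnames.
#' @export
read_cnv_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$cell_id
  m
}
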