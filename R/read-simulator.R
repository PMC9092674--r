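# Read simulator: per-cell FASTQ generation from the haplotype genomes,
# with per-bin Poisson template counts whose mean is proportional to the
# cell's copy number in that bin, a uniform substitution-error model,
# constant Phred qualities, and SE/PE layouts. Templates are confined to
# single bins so per-bin counts are exactly Poisson and depth steps at
# breakpoints are sharp.

#' Expected template count for one bin
#'
#' `lambda = coverage * bin_width / bases_per_template * cn / 2`, where
#' `bases_per_template` is `read_len` (SE) or `2 * read_len` (PE). At CN = 2
#' the resulting mean base depth equals `coverage`; depth is linear in CN and
#' a CN = 0 bin yields no reads.
#'
#' @param bin one `bin_set` row (or a numeric bin width in bp).
#' @param cn integer copy number.
#' @param params a [sim_params()] object.
#' @return the non-negative Poisson mean.
#' @export
expected_reads_per_bin <- function(bin, cn, params) {
  width <- if (is.numeric(bin)) bin else bin$end - bin$start + 1
  bpt <- if (params$layout == "PE") 2 * params$read_len else params$read_len
  params$coverage * width / bpt * (cn / 2)
}

#' Simulate one cell's reads
#'
#' Per bin, `Poisson(lambda)` templates are drawn (see
#' [expected_reads_per_bin()]); each template picks haplotype A or B with
#' probability 1/2 and a uniform start such that the whole template fits
#' inside the haplotype-mapped bin extent. SE emits the template as one read;
#' PE draws a fragment length from `Normal(insert_mean, insert_sd)` truncated
#' below at `2 * read_len` (and clamped to the bin extent) and emits mate 1
#' forward, mate 2 reverse-complemented from the fragment end. Substitution
#' errors hit each base independently with probability `error_rate`
#' (uniformly one of the three other bases); qualities are the constant
#' `base_quality`. Bins whose mapped extent cannot hold a template are
#' skipped with a warning. Consumes the current RNG state.
#'
#' Read names carry the truth tag `cell|hapX|contig|start|mate`, where
#' `start` is the read's own 1-based start on the named haplotype (so with
#' `error_rate = 0` every read equals — or for mate 2, reverse-complements —
#' the haplotype substring at its tag position).
#'
#' @param hap a `hap_genome`.
#' @param bins a `bin_set` on the reference coordinates.
#' @param cnv_row integer copy number per bin (e.g. one noisy-matrix row);
#'   recycled to all-2 if `NULL`.
#' @param params a [sim_params()] object.
#' @return an object of class `read_batch`: list with `cell_id`, `layout`,
#'   `name`, `seq`, `qual`, and for PE additionally `seq2`, `qual2`, `name2`;
#'   plus `bin_index` (per template) for depth accounting.
#' @export
simulate_cell_reads <- function(hap, bins, cnv_row, params) {
  if (is.null(cnv_row)) cnv_row <- rep(2L, nrow(bins))
  stopifnot(length(cnv_row) == nrow(bins))
  rl <- params$read_len
  pe <- params$layout == "PE"
  qual1 <- strrep(intToUtf8(params$base_quality + 33L), rl)

  names_out <- list(); seqs <- list(); starts <- list(); haps_out <- list()
  binidx <- list(); tlens <- list()
  skipped <- 0L
  t_i <- 0L
  for (b in seq_len(nrow(bins))) {
    lambda <- expected_reads_per_bin(bins[b, ], cnv_row[b], params)
    n <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
    if (n == 0L) next
    hap_pick <- sample(c("A", "B"), n, replace = TRUE)
    tl <- if (pe) pmax(2L * rl,
                       as.integer(round(stats::rnorm(n, params$insert_mean,
                                                     params$insert_sd))))
          else rep(rl, n)
    cn_name <- bins$chrom[b]
    for (h in c("A", "B")) {
      sel <- which(hap_pick == h)
      if (length(sel) == 0L) next
      ext <- mapped_bin_extent(hap$events[[h]][[cn_name]],
                               bins$start[b], bins$end[b])
      if (is.null(ext) || ext[2] - ext[1] + 1L < rl ||
          (pe && ext[2] - ext[1] + 1L < 2L * rl)) {
        skipped <- skipped + 1L
        next
      }
      tl_h <- pmin(tl[sel], ext[2] - ext[1] + 1L)
      st <- ext[1] + floor(stats::runif(length(sel)) *
                           (ext[2] - tl_h - ext[1] + 2L))
      st <- as.integer(st)
      t_i <- t_i + 1L
      seqs[[t_i]] <- substring(hap$hap[[h]][[cn_name]], st, st + tl_h - 1L)
      starts[[t_i]] <- st
      haps_out[[t_i]] <- rep(h, length(sel))
      names_out[[t_i]] <- rep(cn_name, length(sel))
      binidx[[t_i]] <- rep(b, length(sel))
      tlens[[t_i]] <- tl_h
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d bin/haplotype extent(s) too short for a template; skipped",
                    skipped), call. = FALSE)
  frag <- unlist(seqs); st <- unlist(starts); hp <- unlist(haps_out)
  cn_of <- unlist(names_out); bi <- unlist(binidx); tl <- unlist(tlens)
  n_t <- length(frag)
  if (n_t == 0L) {
    frag <- character(0); st <- integer(0); hp <- character(0)
    cn_of <- character(0); bi <- integer(0); tl <- integer(0)
  }

  if (!pe) {
    seq1 <- frag
    name1 <- sprintf("%s|hap%s|%s|%d|1", hap$cell_id, hp, cn_of, st)
    seq1 <- apply_seq_errors(seq1, params$error_rate)
    batch <- list(cell_id = hap$cell_id, layout = "SE",
                  name = name1, seq = seq1,
                  qual = rep(qual1, n_t), bin_index = bi)
  } else {
    seq1 <- substr(frag, 1L, rl)
    seq2f <- substr(frag, tl - rl + 1L, tl)
    st2 <- st + tl - rl
    seq2 <- revcomp(seq2f)
    name1 <- sprintf("%s|hap%s|%s|%d|1", hap$cell_id, hp, cn_of, st)
    name2 <- sprintf("%s|hap%s|%s|%d|2", hap$cell_id, hp, cn_of, st2)
    seq1 <- apply_seq_errors(seq1, params$error_rate)
    seq2 <- apply_seq_errors(seq2, params$error_rate)
    batch <- list(cell_id = hap$cell_id, layout = "PE",
                  name = name1, seq = seq1, qual = rep(qual1, n_t),
                  name2 = name2, seq2 = seq2, qual2 = rep(qual1, n_t),
                  bin_index = bi)
  }
  class(batch) <- "read_batch"
  batch
}

# Haplotype-coordinate extent of a reference bin; NULL if fully deleted.
mapped_bin_extent <- function(events, ref_start, ref_end) {
  if (nrow(events) == 0L) return(c(ref_start, ref_end))
  hs <- map_ref_to_hap(events, ref_start)
  he <- map_ref_to_hap(events, ref_end)
  if (is.na(hs)) {
    del <- events[events$kind == "DEL", , drop = FALSE]
    j <- findInterval(ref_start, del$pos)
    nxt <- del$pos[j] + del$length[j]  # first existing base after the del
    if (nxt > ref_end) return(NULL)
    hs <- map_ref_to_hap(events, nxt)
  }
  if (is.na(he)) {
    del <- events[events$kind == "DEL", , drop = FALSE]
    j <- findInterval(ref_end, del$pos)
    prev <- del$pos[j] - 1L
    if (prev < ref_start) return(NULL)
    he <- map_ref_to_hap(events, prev)
  }
  if (is.na(hs) || is.na(he) || he < hs) return(NULL)
  c(hs, he)
}

# Per-base substitution errors at rate p (uniform over the 3 other bases).
apply_seq_errors <- function(seqs, p) {
  if (p <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), p)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[[i]]), n_err[[i]])
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    for (p_k in pos) ch[p_k] <- setdiff(BASES, ch[p_k])[sample.int(3L, 1L)]
    seqs[[i]] <- paste(ch, collapse = "")
  }
  seqs
}

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Per-bin template counts of a read batch
#'
#' @param batch a `read_batch`.
#' @param n_bins total number of bins.
#' @return integer vector of template counts per bin.
#' @export
bin_read_counts <- function(batch, n_bins) {
  tabulate(batch$bin_index, nbins = n_bins)
}

#' Write a read batch as FASTQ
#'
#' SE batches produce `<cell_id>.fastq`; PE batches produce
#' `<cell_id>_1.fastq` / `<cell_id>_2.fastq` with mates in matching order.
#' Standard 4-line records, Phred+33 qualities.
#'
#' @param batch a `read_batch`.
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_fastq <- function(batch, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(names, seqs, quals, path) {
    n <- length(names)
    rec <- character(4L * n)
    if (n > 0L) {
      rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", names)
      rec[seq(2L, by = 4L, length.out = n)] <- seqs
      rec[seq(3L, by = 4L, length.out = n)] <- "+"
      rec[seq(4L, by = 4L, length.out = n)] <- quals
    }
    con <- file(path, "w")
    writeLines(rec, con)
    close(con)
    path
  }
  if (batch$layout == "SE") {
    p <- emit(batch$name, batch$seq, batch$qual,
              file.path(out_dir, paste0(batch$cell_id, ".fastq")))
    invisible(p)
  } else {
    p1 <- emit(batch$name, batch$seq, batch$qual,
               file.path(out_dir, paste0(batch$cell_id, "_1.fastq")))
    p2 <- emit(batch$name2, batch$seq2, batch$qual2,
               file.path(out_dir, paste0(batch$cell_id, "_2.fastq")))
    invisible(c(p1, p2))
  }
}
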