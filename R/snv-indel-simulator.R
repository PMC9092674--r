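# SNV and indel simulators: de novo point mutations and short (4-10 bp)
# insertions/deletions placed at random reference positions, fully private
# per cell (the batch-sharing rule applies to SNPs only).

#' Simulate per-cell SNV profiles
#'
#' Each cell receives `snv_no` distinct, uniformly sampled non-N reference
#' positions, independently across cells. The alternative base is uniform
#' over the three non-reference bases; genotype is HET with probability
#' `het_rate`. Deterministic given `params$seed`.
#'
#' @param params a validated [sim_params()] object.
#' @param genome a `ref_genome`.
#' @return named list (cell0, cell1, ...) of data.frames with columns chrom,
#'   pos, ref, alt, genotype, sorted by (chrom, pos).
#' @export
simulate_snv_profiles <- function(params, genome) {
  validate_params(params)
  cell_ids <- paste0("cell", seq_len(params$cell_no) - 1L)
  order_key <- match(names(genome$seq), names(genome$seq))
  profs <- lapply(seq_len(params$cell_no), function(i) {
    with_stream(derive_seed(params$seed, "snv", "cell", i - 1L), {
      if (params$snv_no == 0L)
        return(data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          genotype = character(0), stringsAsFactors = FALSE))
      rec <- sample_nonN_positions(genome, params$snv_no)
      rec$ref <- base_at(genome, rec$chrom, rec$pos)
      rec$alt <- draw_alt_bases(rec$ref)
      rec$genotype <- sample(c("HET", "HOM"), nrow(rec), replace = TRUE,
                             prob = c(params$het_rate, 1 - params$het_rate))
      rec <- rec[order(match(rec$chrom, names(genome$seq)), rec$pos), ,
                 drop = FALSE]
      rownames(rec) <- NULL
      rec
    })
  })
  stats::setNames(profs, cell_ids)
}

#' Simulate per-cell indel profiles
#'
#' Each cell receives `indel_no` indel records: insertion or deletion with
#' equal probability, length uniform on 4..10 bp, inserted bases i.i.d.
#' uniform over ACGT. Anchors are rejection-sampled so that within a cell the
#' occupied intervals, padded by a 10 bp buffer, are pairwise disjoint (and
#' disjoint from any `avoid` positions) — this guarantees unambiguous genome
#' building and exact round-trip verification. The deletion anchor is the
#' first deleted base: a length-5 deletion at `pos` removes `pos..pos+4`.
#'
#' @param params a validated [sim_params()] object.
#' @param genome a `ref_genome`.
#' @param avoid optional list (one element per cell) of data.frames with
#'   columns chrom, pos giving point-variant sites the indels must keep a
#'   10 bp buffer from.
#' @param max_tries_per_indel rejection-sampling budget before giving up.
#' @return named list of data.frames with columns chrom, pos, kind (INS/DEL),
#'   length, seq (empty for DEL), genotype, sorted by (chrom, pos).
#' @export
simulate_indel_profiles <- function(params, genome, avoid = NULL,
                                    max_tries_per_indel = 100L) {
  validate_params(params)
  lens <- contig_lengths(genome)
  if (max(lens) < 30L)
    stop("contigs too short to host indels with a 10 bp buffer")
  cell_ids <- paste0("cell", seq_len(params$cell_no) - 1L)
  buffer <- 10L
  profs <- lapply(seq_len(params$cell_no), function(i) {
    with_stream(derive_seed(params$seed, "indel", "cell", i - 1L), {
      empty <- data.frame(chrom = character(0), pos = integer(0),
                          kind = character(0), length = integer(0),
                          seq = character(0), genotype = character(0),
                          stringsAsFactors = FALSE)
      if (params$indel_no == 0L) return(empty)
      # occupied intervals per contig, padded by the buffer
      occ <- lapply(names(lens), function(cn) {
        if (is.null(avoid)) return(cbind(numeric(0), numeric(0)))
        av <- avoid[[i]]
        av <- av[av$chrom == cn, , drop = FALSE]
        cbind(av$pos - buffer, av$pos + buffer)
      })
      names(occ) <- names(lens)
      recs <- vector("list", params$indel_no)
      tries <- 0L
      budget <- max_tries_per_indel * params$indel_no + 1000L
      placed <- 0L
      while (placed < params$indel_no) {
        tries <- tries + 1L
        if (tries > budget)
          stop(sprintf("could not place %d non-overlapping indels after %d tries",
                       params$indel_no, budget), call. = FALSE)
        cn <- sample(names(lens), 1L, prob = lens)
        len <- sample(4:10, 1L)
        kind <- if (stats::runif(1) < 0.5) "INS" else "DEL"
        span <- if (kind == "DEL") len else 1L
        pos <- sample.int(lens[[cn]] - span + 1L, 1L)
        lo <- pos - buffer
        hi <- pos + span - 1L + buffer
        o <- occ[[cn]]
        if (nrow(o) > 0L && any(lo <= o[, 2] & hi >= o[, 1])) next
        region <- substring(genome$seq[[cn]], max(1L, pos),
                            min(lens[[cn]], pos + span - 1L))
        if (grepl("N", region, fixed = TRUE)) next
        occ[[cn]] <- rbind(o, c(lo, hi))
        placed <- placed + 1L
        recs[[placed]] <- list(
          chrom = cn, pos = pos, kind = kind, length = len,
          seq = if (kind == "INS")
            paste(sample(BASES, len, replace = TRUE), collapse = "") else "",
          genotype = sample(c("HET", "HOM"), 1L,
                            prob = c(params$het_rate, 1 - params$het_rate)))
      }
      df <- do.call(rbind, lapply(recs, as.data.frame,
                                  stringsAsFactors = FALSE))
      df <- df[order(match(df$chrom, names(lens)), df$pos), , drop = FALSE]
      rownames(df) <- NULL
      df
    })
  })
  stats::setNames(profs, cell_ids)
}

#' Write SNV profiles to TSV
#'
#' One `<cell_id>_snvs.tsv` per cell with columns cell_id, chrom, pos, ref,
#' alt, genotype.
#'
#' @param profiles result of [simulate_snv_profiles()].
#' @param out_dir output directory.
#' @return written paths, invisibly.
#' @export
write_snv_profiles <- function(profiles, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(profiles), function(cid) {
    prof <- profiles[[cid]]
    path <- file.path(out_dir, paste0(cid, "_snvs.tsv"))
    write_tsv(cbind(cell_id = rep(cid, nrow(prof)), prof), path)
    path
  }, character(1))
  invisible(unname(paths))
}

#' Write indel profiles to TSV
#'
#' One `<cell_id>_indels.tsv` per cell with columns cell_id, chrom, pos,
#' kind, length, seq (empty for deletions), genotype.
#'
#' @param profiles result of [simulate_indel_profiles()].
#' @param out_dir output directory.
#' @return written paths, invisibly.
#' @export
write_indel_profiles <- function(profiles, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(profiles), function(cid) {
    prof <- profiles[[cid]]
    path <- file.path(out_dir, paste0(cid, "_indels.tsv"))
    write_tsv(cbind(cell_id = rep(cid, nrow(prof)), prof), path)
    path
  }, character(1))
  invisible(unname(paths))
}
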