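# Genome builder: applies each cell's point variants and indels to the
# reference to produce two diploid haplotype sequences with coordinate maps
# back to the reference, and verifies the round trip (generating-accuracy).
#
# Copy number is deliberately NOT materialized here: the read simulator
# realizes CNV as depth, which keeps haplotype coordinates stable and makes
# point-variant verification exact.

#' Build a cell's diploid mutated genome
#'
#' Homozygous variants are applied to both haplotypes; heterozygous variants
#' to exactly one haplotype chosen by a fair coin per variant (the "phase").
#' Substitutions never shift coordinates; indels are applied through a
#' piecewise reconstruction so edits never corrupt one another, which is
#' guaranteed well-defined by the upstream 10 bp non-overlap buffer.
#' Consumes the current RNG state (for phase only).
#'
#' @param genome a `ref_genome`.
#' @param snps,snvs data.frames with columns chrom, pos, ref, alt, genotype
#'   (either may be `NULL`).
#' @param indels data.frame with columns chrom, pos, kind, length, seq,
#'   genotype (or `NULL`).
#' @param cell_id cell identifier stored in the result.
#' @return an object of class `hap_genome`: list with `cell_id`, `hap` (list
#'   `A`/`B` of named contig sequences), `events` (per haplotype, per contig,
#'   the ascending indel table driving the coordinate map), and `phase`
#'   (data.frame class, chrom, pos, hap in {A, B, both}).
#' @export
build_cell_genome <- function(genome, snps = NULL, snvs = NULL, indels = NULL,
                              cell_id = "cell0") {
  subs <- rbind(
    if (!is.null(snps) && nrow(snps))
      data.frame(class = "snp", chrom = snps$chrom, pos = snps$pos,
                 ref = snps$ref, alt = snps$alt, genotype = snps$genotype,
                 stringsAsFactors = FALSE),
    if (!is.null(snvs) && nrow(snvs))
      data.frame(class = "snv", chrom = snvs$chrom, pos = snvs$pos,
                 ref = snvs$ref, alt = snvs$alt, genotype = snvs$genotype,
                 stringsAsFactors = FALSE))
  ind <- if (!is.null(indels) && nrow(indels))
    data.frame(class = "indel", chrom = indels$chrom, pos = indels$pos,
               kind = indels$kind, length = indels$length, seq = indels$seq,
               genotype = indels$genotype, stringsAsFactors = FALSE)
  lens <- contig_lengths(genome)
  check_in_range <- function(chrom, pos, span) {
    bad <- pos < 1L | pos + span - 1L > lens[chrom]
    if (any(bad))
      stop(sprintf("variant out of contig range at %s:%d",
                   chrom[bad][1], pos[bad][1]), call. = FALSE)
  }
  if (!is.null(subs)) check_in_range(subs$chrom, subs$pos, 1L)
  if (!is.null(ind))
    check_in_range(ind$chrom, ind$pos, ifelse(ind$kind == "DEL",
                                              ind$length, 1L))

  phase_of <- function(gt) {
    ifelse(gt == "HOM", "both", ifelse(stats::runif(length(gt)) < 0.5,
                                       "A", "B"))
  }
  phase_rows <- list()
  if (!is.null(subs)) {
    subs$hap <- phase_of(subs$genotype)
    phase_rows$subs <- subs[, c("class", "chrom", "pos", "hap")]
  }
  if (!is.null(ind)) {
    ind$hap <- phase_of(ind$genotype)
    phase_rows$ind <- ind[, c("class", "chrom", "pos", "hap")]
  }
  phase <- if (length(phase_rows)) do.call(rbind, phase_rows)
           else data.frame(class = character(0), chrom = character(0),
                           pos = integer(0), hap = character(0))
  rownames(phase) <- NULL

  haps <- list(A = genome$seq, B = genome$seq)
  events <- list(A = list(), B = list())
  for (h in c("A", "B")) {
    s_h <- if (!is.null(subs)) subs[subs$hap %in% c(h, "both"), , drop = FALSE]
    i_h <- if (!is.null(ind)) ind[ind$hap %in% c(h, "both"), , drop = FALSE]
    for (cn in names(genome$seq)) {
      s_c <- if (!is.null(s_h)) s_h[s_h$chrom == cn, , drop = FALSE]
      i_c <- if (!is.null(i_h)) i_h[i_h$chrom == cn, , drop = FALSE]
      if (!is.null(i_c) && nrow(i_c))
        i_c <- i_c[order(i_c$pos), , drop = FALSE]
      assert_disjoint(s_c, i_c, cn)
      haps[[h]][[cn]] <- apply_edits(genome$seq[[cn]], s_c, i_c)
      events[[h]][[cn]] <- if (!is.null(i_c) && nrow(i_c))
        i_c[, c("kind", "pos", "length")]
      else data.frame(kind = character(0), pos = integer(0),
                      length = integer(0))
    }
  }
  structure(list(cell_id = cell_id, hap = haps, events = events,
                 phase = phase),
            class = "hap_genome")
}

# Fail loudly if variant intervals overlap (upstream contracts forbid it).
assert_disjoint <- function(subs, indels, contig) {
  iv <- rbind(
    if (!is.null(subs) && nrow(subs)) cbind(subs$pos, subs$pos),
    if (!is.null(indels) && nrow(indels))
      cbind(indels$pos,
            ifelse(indels$kind == "DEL",
                   indels$pos + indels$length - 1L, indels$pos)))
  if (is.null(iv) || nrow(iv) < 2L) return(invisible())
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
    stop("overlapping variant intervals on contig ", contig, call. = FALSE)
  invisible()
}

# One contig, one haplotype: substitutions by vector assignment, then indels
# (ascending) by piecewise reconstruction.
apply_edits <- function(seq, subs, indels) {
  have_subs <- !is.null(subs) && nrow(subs) > 0L
  have_ind <- !is.null(indels) && nrow(indels) > 0L
  if (!have_subs && !have_ind) return(seq)
  if (have_subs) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    ch[subs$pos] <- subs$alt
    seq <- paste(ch, collapse = "")
  }
  if (have_ind) {
    pieces <- character(0)
    last <- 1L
    for (k in seq_len(nrow(indels))) {
      pos <- indels$pos[k]
      len <- indels$length[k]
      if (indels$kind[k] == "INS") {
        pieces <- c(pieces, substring(seq, last, pos), indels$seq[k])
        last <- pos + 1L
      } else {
        pieces <- c(pieces, substring(seq, last, pos - 1L))
        last <- pos + len
      }
    }
    pieces <- c(pieces, substring(seq, last, nchar(seq)))
    seq <- paste(pieces, collapse = "")
  }
  seq
}

#' Map reference positions to haplotype positions
#'
#' Insertions of length L anchored at `a` shift positions `> a` by `+L`;
#' deletions starting at `p` of length L make positions `p..p+L-1` undefined
#' (`NA`) and shift positions `>= p+L` by `-L`. The map is monotone wherever
#' defined.
#'
#' @param events one haplotype/contig event table from a `hap_genome`
#'   (columns kind, pos, length, ascending in pos).
#' @param pos integer vector of 1-based reference positions.
#' @return integer vector of haplotype positions, `NA` inside deletions.
#' @export
map_ref_to_hap <- function(events, pos) {
  if (nrow(events) == 0L) return(as.integer(pos))
  ins <- events[events$kind == "INS", , drop = FALSE]
  del <- events[events$kind == "DEL", , drop = FALSE]
  shift_ins <- if (nrow(ins)) {
    cum <- cumsum(ins$length)
    idx <- findInterval(pos - 1L, ins$pos)
    ifelse(idx > 0L, cum[pmax(idx, 1L)], 0L)
  } else 0L
  if (nrow(del)) {
    dend <- del$pos + del$length - 1L
    idx <- findInterval(pos - 1L, dend)
    cum <- cumsum(del$length)
    shift_del <- ifelse(idx > 0L, cum[pmax(idx, 1L)], 0L)
    j <- findInterval(pos, del$pos)
    inside <- j > 0L & pos <= dend[pmax(j, 1L)]
  } else {
    shift_del <- 0L
    inside <- FALSE
  }
  out <- as.integer(pos + shift_ins - shift_del)
  out[inside] <- NA_integer_
  out
}

#' Verify generating-accuracy of a built genome
#'
#' For every ground-truth variant, checks the expected base(s) or sequence at
#' the coordinate-mapped position on the haplotype(s) implied by its
#' genotype/phase, and returns the verified fraction. A freshly built cell
#' verifies at 1.0 for every variant class; an empty profile returns 1.0.
#'
#' Checks per class: substitutions — the mapped base equals `alt`;
#' insertions — the inserted sequence follows the mapped anchor; deletions —
#' the deleted reference positions are unmapped and the sequence after the
#' junction equals the reference downstream of the deleted span.
#'
#' @param genome the `ref_genome` the cell was built from.
#' @param profile a variant table (SNP/SNV: chrom, pos, ref, alt; indel:
#'   chrom, pos, kind, length, seq).
#' @param hap the cell's `hap_genome`.
#' @param class `"snp"`, `"snv"` or `"indel"` (controls which phase records
#'   and checks apply).
#' @return fraction of verified variants in `[0, 1]`.
#' @export
verify_generating_accuracy <- function(genome, profile, hap,
                                       class = c("snv", "snp", "indel")) {
  class <- match.arg(class)
  if (is.null(profile) || nrow(profile) == 0L) return(1.0)
  ph <- hap$phase[hap$phase$class == class, , drop = FALSE]
  key <- paste(profile$chrom, profile$pos)
  hap_of <- ph$hap[match(key, paste(ph$chrom, ph$pos))]
  if (anyNA(hap_of))
    stop("profile contains variants with no phase record", call. = FALSE)
  ok <- logical(nrow(profile))
  for (k in seq_len(nrow(profile))) {
    targets <- if (hap_of[k] == "both") c("A", "B") else hap_of[k]
    ok[k] <- all(vapply(targets, function(h) {
      ev <- hap$events[[h]][[profile$chrom[k]]]
      hseq <- hap$hap[[h]][[profile$chrom[k]]]
      if (class %in% c("snp", "snv")) {
        m <- map_ref_to_hap(ev, profile$pos[k])
        !is.na(m) && substring(hseq, m, m) == profile$alt[k]
      } else if (profile$kind[k] == "INS") {
        m <- map_ref_to_hap(ev, profile$pos[k])
        !is.na(m) &&
          substring(hseq, m + 1L, m + profile$length[k]) == profile$seq[k]
      } else {
        check_deletion(genome, ev, hseq, profile$chrom[k],
                       profile$pos[k], profile$length[k])
      }
    }, logical(1)))
  }
  mean(ok)
}

check_deletion <- function(genome, events, hseq, chrom, pos, len) {
  ref <- genome$seq[[chrom]]
  span <- map_ref_to_hap(events, pos:(pos + len - 1L))
  if (!all(is.na(span))) return(FALSE)
  junction <- if (pos > 1L) map_ref_to_hap(events, pos - 1L) else 0L
  if (is.na(junction)) return(FALSE)
  after_ref_start <- pos + len
  k <- min(10L, nchar(ref) - after_ref_start + 1L)
  if (k <= 0L) return(nchar(hseq) == junction)  # deletion at contig end
  substring(hseq, junction + 1L, junction + k) ==
    substring(ref, after_ref_start, after_ref_start + k - 1L)
}

#' Write a cell's haplotype FASTAs and phase table
#'
#' Writes `<cell_id>_hapA.fasta`, `<cell_id>_hapB.fasta` (contig names
#' preserved) and `<cell_id>_phase.tsv` — the builder's phase ground truth
#' (class, chrom, pos, hap) needed to re-verify the genomes from files.
#'
#' @param hap a `hap_genome`.
#' @param out_dir output directory (created if missing).
#' @return named character vector of paths, invisibly.
#' @export
write_cell_fastas <- function(hap, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pa <- file.path(out_dir, paste0(hap$cell_id, "_hapA.fasta"))
  pb <- file.path(out_dir, paste0(hap$cell_id, "_hapB.fasta"))
  write_fasta(ref_genome(hap$hap$A), pa)
  write_fasta(ref_genome(hap$hap$B), pb)
  pp <- file.path(out_dir, paste0(hap$cell_id, "_phase.tsv"))
  write_tsv(hap$phase, pp)
  invisible(c(hapA = pa, hapB = pb, phase = pp))
}
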