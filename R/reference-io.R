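# Reference genome and SNP-database IO, plus the synthetic fixture
# generators that make the whole pipeline runnable with no downloads.

#' Construct a reference-genome object
#'
#' @param seqs named character vector, contig name -> sequence over
#'   `{A,C,G,T,N}` (lowercase accepted, uppercased here).
#' @return an object of class `ref_genome`.
#' @export
ref_genome <- function(seqs) {
  if (length(seqs) == 0L) stop("reference genome has no contigs")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("contig names must be non-empty")
  if (anyDuplicated(nm)) stop("duplicate contig name: ", nm[duplicated(nm)][1])
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty contig sequence: ", nm[!nzchar(seqs)][1])
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0)
      stop(sprintf("contig '%s': invalid character '%s' at position %d",
                   nm[[i]], substr(seqs[[i]], bad, bad), bad), call. = FALSE)
  }
  structure(list(seq = seqs), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("Reference genome: %d contig(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of a reference genome
#' @param genome a `ref_genome`.
#' @return named integer vector of contig lengths, in contig order.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(nchar(genome$seq), names(genome$seq))
}

#' Read a FASTA file into a reference genome
#'
#' Multi-contig and wrapped-line FASTA are supported (parsing is delegated to
#' Biostrings). Headers are truncated at the first whitespace, sequences are
#' uppercased, and any character outside `{A,C,G,T,N}` is an error naming the
#' contig and offending position.
#'
#' @param path FASTA file path.
#' @return a `ref_genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  ref_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' `read_fasta(write_fasta(g, path))` reproduces `g` exactly.
#'
#' @param genome a `ref_genome`.
#' @param path output path.
#' @param line_width sequence-line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  if (!inherits(genome, "ref_genome") || length(genome$seq) == 0L)
    stop("cannot write an empty genome")
  if (line_width < 1L) stop("line_width must be >= 1")
  set <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

#' Generate a synthetic reference genome
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`;
#' no N bases are emitted. Contigs are named `"sim1"`, `"sim2"`, ... and the
#' result is byte-identical for identical seeds.
#'
#' @param n_contigs number of contigs.
#' @param contig_len length of each contig in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed master seed.
#' @return a `ref_genome`.
#' @export
generate_synthetic_reference <- function(n_contigs = 1L, contig_len = 2e6,
                                         gc = 0.5, seed = 1L) {
  stopifnot(n_contigs >= 1L, contig_len >= 1, gc >= 0, gc <= 1)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_contigs), function(i) {
    with_stream(derive_seed(seed, "synthetic-reference", i), {
      paste(sample(names(prob), contig_len, replace = TRUE, prob = prob),
            collapse = "")
    })
  }, character(1))
  names(seqs) <- paste0("sim", seq_len(n_contigs))
  ref_genome(seqs)
}

# Uniform sample (without replacement) of n positions among non-N sites.
# Returns a data.frame(chrom, pos) in genome contig order, sorted by pos.
sample_nonN_positions <- function(genome, n) {
  per <- lapply(names(genome$seq), function(cn) {
    s <- genome$seq[[cn]]
    if (grepl("N", s, fixed = TRUE)) {
      which(strsplit(s, "", fixed = TRUE)[[1]] != "N")
    } else {
      seq_len(nchar(s))
    }
  })
  counts <- lengths(per)
  total <- sum(counts)
  if (n > total)
    stop(sprintf("requested %d positions but only %d non-N sites exist",
                 n, total))
  idx <- sort(sample.int(total, n))
  ends <- cumsum(counts)
  contig_i <- findInterval(idx - 1L, ends) + 1L
  offset <- idx - c(0L, ends)[contig_i]
  pos <- vapply(seq_along(idx),
                function(k) per[[contig_i[[k]]]][[offset[[k]]]], integer(1))
  data.frame(chrom = names(genome$seq)[contig_i], pos = pos,
             stringsAsFactors = FALSE)
}

# Vectorized base lookup.
base_at <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    out[sel] <- substring(genome$seq[[cn]], pos[sel], pos[sel])
  }
  out
}

BASES <- c("A", "C", "G", "T")

# For each ref base draw a uniformly random different base.
draw_alt_bases <- function(ref) {
  k <- sample.int(3L, length(ref), replace = TRUE)
  vapply(seq_along(ref), function(i) setdiff(BASES, ref[[i]])[[k[[i]]]],
         character(1))
}

#' Generate a synthetic SNP database
#'
#' Samples `n_records` distinct positions uniformly (without replacement)
#' among the genome's non-N sites; `ref` is the genome base at each position,
#' `alt` is uniform over the three other bases, and rsids are sequential
#' (`rsS000001`, ...) in (chrom, pos) order. The `rsS` prefix marks the
#' records as synthetic.
#'
#' @param genome a `ref_genome`.
#' @param n_records number of SNP records.
#' @param seed master seed.
#' @return a `snp_db` data.frame with columns chrom, pos, rsid, ref, alt.
#' @export
generate_synthetic_dbsnp <- function(genome, n_records, seed = 1L) {
  stopifnot(n_records >= 1L)
  db <- with_stream(derive_seed(seed, "synthetic-dbsnp"), {
    rec <- sample_nonN_positions(genome, n_records)
    rec <- rec[order(match(rec$chrom, names(genome$seq)), rec$pos), ,
               drop = FALSE]
    rec$ref <- base_at(genome, rec$chrom, rec$pos)
    rec$alt <- draw_alt_bases(rec$ref)
    rec
  })
  db$rsid <- sprintf("rsS%06d", seq_len(nrow(db)))
  db <- db[, c("chrom", "pos", "rsid", "ref", "alt")]
  rownames(db) <- NULL
  class(db) <- c("snp_db", "data.frame")
  db
}

#' Write a SNP database as TSV
#'
#' @param db a `snp_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dbsnp_table <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\trsid\tref\talt", con)
  utils::write.table(db, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a SNP-database TSV
#'
#' The dialect is five tab-separated columns `chrom, pos (1-based), rsid,
#' ref, alt`; lines starting with `#` are headers and skipped. Structural
#' defects (column count, non-integer position, multi-base or non-ACGT
#' allele, `ref == alt`, duplicate `(chrom, pos)`) are errors reported with
#' their line number. When a genome is attached, records whose `ref` does not
#' match the genome base or whose position exceeds the contig are dropped and
#' their count reported via a warning.
#'
#' @param path TSV path.
#' @param genome optional `ref_genome` for consistency filtering.
#' @return a `snp_db` data.frame sorted by (chrom, pos).
#' @export
parse_dbsnp_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("SNP database file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("SNP database has no records: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 5L))
    stop(sprintf("malformed SNP record at line %d: expected 5 columns, got %d",
                 lineno[nc != 5L][1], nc[nc != 5L][1]), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stop(sprintf("malformed SNP record at line %d: non-integer position",
                 lineno[is.na(pos)][1]), call. = FALSE)
  badal <- !(m[, 4] %in% BASES) | !(m[, 5] %in% BASES)
  if (any(badal))
    stop(sprintf("malformed SNP record at line %d: alleles must be single A/C/G/T bases",
                 lineno[badal][1]), call. = FALSE)
  same <- m[, 4] == m[, 5]
  if (any(same))
    stop(sprintf("invalid SNP record at line %d: ref equals alt",
                 lineno[same][1]), call. = FALSE)
  db <- data.frame(chrom = m[, 1], pos = pos, rsid = m[, 3],
                   ref = m[, 4], alt = m[, 5], stringsAsFactors = FALSE)
  dup <- duplicated(db[, c("chrom", "pos")])
  if (any(dup))
    stop(sprintf("duplicate SNP site at line %d (%s:%d)",
                 lineno[dup][1], db$chrom[dup][1], db$pos[dup][1]),
         call. = FALSE)
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    known <- db$chrom %in% names(lens)
    inrange <- known & db$pos <= lens[db$chrom] & db$pos >= 1L
    ok <- inrange
    ok[inrange] <- base_at(genome, db$chrom[inrange], db$pos[inrange]) ==
      db$ref[inrange]
    n_drop <- sum(!ok)
    if (n_drop > 0L) {
      warning(sprintf("dropped %d SNP record(s) inconsistent with the reference genome",
                      n_drop), call. = FALSE)
      db <- db[ok, , drop = FALSE]
    }
    ord <- order(match(db$chrom, names(lens)), db$pos)
  } else {
    ord <- order(match(db$chrom, unique(db$chrom)), db$pos)
  }
  db <- db[ord, , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("snp_db", "data.frame")
  db
}
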