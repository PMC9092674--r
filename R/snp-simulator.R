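# SNP simulator: per-cell SNP profiles drawn from a SNP database, with a
# batch-shared core so that cells in one batch have similar but slightly
# varied SNP landscapes.

#' Simulate per-cell SNP profiles
#'
#' A shared core of `round(shared_snp_frac * snp_no)` database records is
#' sampled once (without replacement) and appears in every cell with one
#' batch-wide genotype per site; each cell then receives its remaining
#' private records from the leftover pool, disjointly across cells, so the
#' shared fraction is exact rather than approximate. Genotypes are HET with
#' probability `het_rate`, HOM otherwise. Fully deterministic given
#' `params$seed`; adding cells never changes the draws of earlier cells.
#'
#' @param params a validated [sim_params()] object.
#' @param db a `snp_db` (see [parse_dbsnp_table()] /
#'   [generate_synthetic_dbsnp()]).
#' @return an object of class `snp_profiles`: a list with `cells` (named list
#'   of per-cell data.frames with columns chrom, pos, rsid, ref, alt,
#'   genotype, sorted by (chrom, pos)) and `shared` (the shared-core
#'   data.frame).
#' @export
simulate_snp_profiles <- function(params, db) {
  validate_params(params)
  n_cells <- params$cell_no
  snp_no <- params$snp_no
  cell_ids <- paste0("cell", seq_len(n_cells) - 1L)
  if (snp_no == 0L) {
    empty <- db[0L, , drop = FALSE]
    empty$genotype <- character(0)
    cells <- stats::setNames(rep(list(empty), n_cells), cell_ids)
    return(structure(list(cells = cells, shared = empty),
                     class = "snp_profiles"))
  }
  shared_count <- as.integer(round_half_up(params$shared_snp_frac * snp_no))
  private_count <- snp_no - shared_count
  need <- shared_count + n_cells * private_count
  if (nrow(db) < need)
    stop(sprintf("SNP database too small: %d records available, %d needed (%d shared + %d cells x %d private)",
                 nrow(db), need, shared_count, n_cells, private_count),
         call. = FALSE)

  chrom_rank <- match(db$chrom, unique(db$chrom))
  shared <- with_stream(derive_seed(params$seed, "snp", "shared"), {
    idx <- sample.int(nrow(db), shared_count)
    gt <- sample(c("HET", "HOM"), shared_count, replace = TRUE,
                 prob = c(params$het_rate, 1 - params$het_rate))
    list(idx = idx, gt = gt)
  })
  pool <- setdiff(seq_len(nrow(db)), shared$idx)

  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    drawn <- with_stream(derive_seed(params$seed, "snp", "cell", i - 1L), {
      pi <- if (private_count > 0L)
        pool[sample.int(length(pool), private_count)] else integer(0)
      gt <- if (private_count > 0L)
        sample(c("HET", "HOM"), private_count, replace = TRUE,
               prob = c(params$het_rate, 1 - params$het_rate)) else character(0)
      list(idx = pi, gt = gt)
    })
    pool <- setdiff(pool, drawn$idx)
    idx <- c(shared$idx, drawn$idx)
    prof <- db[idx, , drop = FALSE]
    prof$genotype <- c(shared$gt, drawn$gt)
    ord <- order(chrom_rank[idx], prof$pos)
    prof <- prof[ord, , drop = FALSE]
    rownames(prof) <- NULL
    class(prof) <- "data.frame"
    cells[[i]] <- prof
  }
  names(cells) <- cell_ids

  shared_df <- db[shared$idx, , drop = FALSE]
  shared_df$genotype <- shared$gt
  shared_df <- shared_df[order(chrom_rank[shared$idx], shared_df$pos), ,
                         drop = FALSE]
  rownames(shared_df) <- NULL
  class(shared_df) <- "data.frame"
  structure(list(cells = cells, shared = shared_df), class = "snp_profiles")
}

#' Write SNP profiles to TSV
#'
#' One TSV per cell (`<cell_id>_snps.tsv`, columns cell_id, chrom, pos, rsid,
#' ref, alt, genotype, sorted by (chrom, pos)) plus one batch-level
#' `shared_snps.tsv` of the shared core.
#'
#' @param profiles an `snp_profiles` object.
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_snp_profiles <- function(profiles, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cid in names(profiles$cells)) {
    prof <- profiles$cells[[cid]]
    out <- cbind(cell_id = rep(cid, nrow(prof)), prof)
    path <- file.path(out_dir, paste0(cid, "_snps.tsv"))
    write_tsv(out, path)
    paths <- c(paths, path)
  }
  shared_path <- file.path(out_dir, "shared_snps.tsv")
  write_tsv(profiles$shared, shared_path)
  invisible(c(paths, shared_path))
}

# deterministic TSV writer used by all profile writers
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = NA, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}
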