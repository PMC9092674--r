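# Batch pipeline: wires the simulators together (profiles -> mutated
# genomes -> reads), writes the output tree and a reproducibility manifest,
# and re-verifies finished runs from their files.
#
# Output layout under params$out_dir:
#   profiles/  per-cell variant TSVs (+ shared_snps.tsv for SNP runs)
#   fasta/     per-cell haplotype FASTAs + phase TSVs
#   fastq/     per-cell FASTQ (SE: cellN.fastq; PE: cellN_1/_2.fastq)
#   cnv/       CNV matrices, clusters, breakpoints, segments (cnv mode)
#   manifest.json, run.log

#' Generate the synthetic reference + SNP-database fixture
#'
#' Writes `reference.fasta` and `dbsnp.tsv` under `out_dir`, so every other
#' command can run with no external downloads. Deterministic per seed.
#'
#' @param out_dir output directory.
#' @param n_contigs,contig_len,gc see [generate_synthetic_reference()].
#' @param n_snps SNP-database size (must not exceed the non-N genome size).
#' @param seed master seed.
#' @return named character vector with paths `ref` and `db`.
#' @export
run_fixture <- function(out_dir, n_contigs = 1L, contig_len = 2e6, gc = 0.5,
                        n_snps = 10000L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_synthetic_reference(n_contigs, contig_len, gc, seed)
  db <- generate_synthetic_dbsnp(genome, n_snps, seed)
  ref_path <- file.path(out_dir, "reference.fasta")
  db_path <- file.path(out_dir, "dbsnp.tsv")
  write_fasta(genome, ref_path)
  write_dbsnp_table(db, db_path)
  c(ref = ref_path, db = db_path)
}

#' Run a full simulation batch
#'
#' Modes mirror the four simulators:
#' * `"snp"`, `"snv"`, `"indel"` — per-cell variant profiles of that class,
#'   diploid mutated genomes, and (optionally) reads at flat CN = 2 depth;
#' * `"cnv"` — the cells-by-bins CNV ground truth (clean + noisy matrices,
#'   subclone labels, breakpoints, segments) with per-cell reads whose
#'   per-bin depth follows the noisy matrix row; genomes carry no point
#'   variants in this mode.
#'
#' Everything is deterministic given `params$seed`; re-running with the same
#' parameters reproduces every output byte for byte.
#'
#' @param params a validated [sim_params()] object with `ref_path` set (and
#'   `snp_db_path` for SNP mode).
#' @param mode one of `"snp"`, `"snv"`, `"indel"`, `"cnv"`.
#' @param fasta write per-cell haplotype FASTAs (default `TRUE`).
#' @param fastq write per-cell FASTQ reads (default `TRUE`).
#' @return invisibly, a list with `mode`, `params`, `profiles`, `accuracy`
#'   (per-cell generating-accuracy), `cnv` (cnv mode), `bin_counts` (per-cell
#'   template counts per bin when reads were simulated), and `manifest_path`.
#' @export
run_pipeline <- function(params, mode = c("snp", "snv", "indel", "cnv"),
                         fasta = TRUE, fastq = TRUE) {
  mode <- match.arg(mode)
  validate_params(params)
  if (is.null(params$ref_path)) stop("params$ref_path is required")
  genome <- read_fasta(params$ref_path)
  out <- params$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out, "run.log"), "w")
  on.exit(close(log_con))
  logline <- function(...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       sprintf(...)), log_con)
  }
  logline("run start: mode=%s cells=%d seed=%d", mode, params$cell_no,
          params$seed)

  cell_ids <- paste0("cell", seq_len(params$cell_no) - 1L)
  profiles <- NULL
  cnv <- NULL

  if (mode == "snp") {
    if (is.null(params$snp_db_path))
      stop("params$snp_db_path is required for SNP mode")
    db <- parse_dbsnp_table(params$snp_db_path, genome)
    profiles <- simulate_snp_profiles(params, db)
    write_snp_profiles(profiles, file.path(out, "profiles"))
  } else if (mode == "snv") {
    profiles <- simulate_snv_profiles(params, genome)
    write_snv_profiles(profiles, file.path(out, "profiles"))
  } else if (mode == "indel") {
    profiles <- simulate_indel_profiles(params, genome)
    write_indel_profiles(profiles, file.path(out, "profiles"))
  } else {
    cnv <- with_stream(derive_seed(params$seed, "cnv", "matrix"), {
      bins <- make_bins(genome, params$bin_len)
      segs <- draw_segments(bins, params$seg_no)
      assignment <- assign_clusters(params$cell_no, params$cluster_no,
                                    params$normal_frac)
      mat <- if (params$cluster_no > 0L) {
        clones <- draw_clone_profiles(segs, params$cluster_no, params$max_cn,
                                      params$p_neutral)
        build_matrix(assignment, clones, segs, bins)
      } else {
        build_matrix(assignment,
                     matrix(integer(0), nrow = 0, ncol = nrow(segs$segments)),
                     segs, bins)
      }
      inject_noise(mat, params$noise_rate, params$max_cn)
    })
    write_cnv_outputs(cnv, file.path(out, "cnv"))
    logline("cnv ground truth written: %d bins, %d segments",
            nrow(cnv$bins), nrow(cnv$segments$segments))
  }
  logline("profiles done")

  bins <- make_bins(genome, params$bin_len)
  accuracy <- stats::setNames(numeric(0), character(0))
  bin_counts <- list()
  for (i in seq_along(cell_ids)) {
    cid <- cell_ids[[i]]
    prof <- if (mode == "snp") profiles$cells[[cid]]
            else if (mode %in% c("snv", "indel")) profiles[[cid]]
    hap <- with_stream(derive_seed(params$seed, "genome", i - 1L), {
      build_cell_genome(
        genome,
        snps = if (mode == "snp") prof,
        snvs = if (mode == "snv") prof,
        indels = if (mode == "indel") prof,
        cell_id = cid)
    })
    if (mode != "cnv") {
      cls <- mode
      accuracy[[cid]] <- verify_generating_accuracy(genome, prof, hap, cls)
    }
    if (fasta) write_cell_fastas(hap, file.path(out, "fasta"))
    logline("%s: genome built", cid)
    if (fastq) {
      cn_row <- if (mode == "cnv") cnv$noisy[cid, ] else NULL
      batch <- with_stream(derive_seed(params$seed, "reads", i - 1L),
                           simulate_cell_reads(hap, bins, cn_row, params))
      write_fastq(batch, file.path(out, "fastq"))
      bin_counts[[cid]] <- bin_read_counts(batch, nrow(bins))
      logline("%s: %d templates", cid, length(batch$bin_index))
    }
  }

  manifest_path <- write_manifest(params, mode, out)
  logline("run complete")
  invisible(list(mode = mode, params = params, profiles = profiles,
                 accuracy = accuracy, cnv = cnv, bin_counts = bin_counts,
                 manifest_path = manifest_path))
}

# Manifest: params snapshot (minus out_dir, which is where the manifest
# lives), seed, package version, and md5 checksums of every output file
# keyed by repo-relative path. Deliberately contains no wall-clock state, so
# identical (params, seed) runs yield byte-identical manifests; timestamps
# live in run.log.
write_manifest <- function(params, mode, out) {
  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, c("manifest.json", "run.log"))
  sums <- as.list(tools::md5sum(file.path(out, files)))
  names(sums) <- files
  snap <- unclass(params)
  snap$out_dir <- NULL
  snap[vapply(snap, is.null, logical(1))] <- NULL
  manifest <- list(
    tool = "scDNAsim",
    version = as.character(utils::packageVersion("scDNAsim")),
    mode = mode,
    seed = params$seed,
    params = snap,
    files = sums)
  path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Re-verify a finished run from its files
#'
#' Recomputes the generating-accuracy of every cell and variant class in a
#' run directory, using only the written ground truth: the per-cell profile
#' TSVs, the phase TSVs and the haplotype FASTAs. Coordinate maps are rebuilt
#' from the indel profiles plus phase, so the check is independent of the
#' in-memory objects that produced the run.
#'
#' @param run_dir a directory produced by [run_pipeline()] (any point-variant
#'   mode), containing `profiles/` and `fasta/`.
#' @return a data.frame with columns class, cell_id, accuracy; the per-class
#'   averages are attached as attribute `"class_means"` and printed.
#' @export
verify_run <- function(run_dir) {
  prof_dir <- file.path(run_dir, "profiles")
  fasta_dir <- file.path(run_dir, "fasta")
  if (!dir.exists(prof_dir) || !dir.exists(fasta_dir))
    stop("run directory is missing profiles/ or fasta/: ", run_dir)
  suffixes <- c(snp = "_snps.tsv", snv = "_snvs.tsv", indel = "_indels.tsv")
  rows <- list()
  found_any <- FALSE
  for (cls in names(suffixes)) {
    paths <- sort(list.files(prof_dir, pattern = paste0(suffixes[[cls]], "$"),
                             full.names = TRUE))
    paths <- paths[basename(paths) != "shared_snps.tsv"]
    for (path in paths) {
      found_any <- TRUE
      cid <- sub(paste0(suffixes[[cls]], "$"), "", basename(path))
      prof <- read_tsv(path)
      if (cls == "indel" && nrow(prof) > 0L)
        prof$seq[is.na(prof$seq)] <- ""
      hap <- load_written_cell(fasta_dir, cid, prof, cls)
      acc <- verify_generating_accuracy(hap$ref_placeholder, prof, hap, cls)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, cell_id = cid, accuracy = acc, stringsAsFactors = FALSE)
    }
  }
  if (!found_any) stop("no variant profiles found under ", prof_dir)
  res <- do.call(rbind, rows)
  means <- tapply(res$accuracy, res$class, mean)
  attr(res, "class_means") <- means
  for (cls in names(means))
    message(sprintf("%-6s average generating-accuracy: %.1f%%",
                    cls, 100 * means[[cls]]))
  res
}

# Reassemble a verification-ready hap_genome from written files. The
# reference is reconstructed by inverting the cell's own edits where needed;
# for deletion checks the junction is compared against the written reference
# only through positions outside any variant, so using the hapA/hapB pair
# plus phase suffices. We additionally need the reference for deletion
# junction checks, so it is rebuilt from the run's FASTAs via the phase
# table: a position deleted on one haplotype is intact on the other unless
# HOM, in which case the profile's own coordinates provide the bases.
load_written_cell <- function(fasta_dir, cid, prof, cls) {
  ha <- read_fasta(file.path(fasta_dir, paste0(cid, "_hapA.fasta")))
  hb <- read_fasta(file.path(fasta_dir, paste0(cid, "_hapB.fasta")))
  phase <- read_tsv(file.path(fasta_dir, paste0(cid, "_phase.tsv")))
  events <- list(A = list(), B = list())
  contigs <- names(ha$seq)
  for (h in c("A", "B")) {
    for (cn in contigs) {
      ev <- data.frame(kind = character(0), pos = integer(0),
                       length = integer(0))
      if (cls == "indel" && nrow(prof) > 0L) {
        key <- paste(prof$chrom, prof$pos)
        ph <- phase[phase$class == "indel", , drop = FALSE]
        hap_of <- ph$hap[match(key, paste(ph$chrom, ph$pos))]
        sel <- prof$chrom == cn & hap_of %in% c(h, "both")
        if (any(sel)) {
          ev <- prof[sel, c("kind", "pos", "length")]
          ev <- ev[order(ev$pos), , drop = FALSE]
        }
      }
      events[[h]][[cn]] <- ev
    }
  }
  ref <- reconstruct_reference(ha, hb, events, prof, cls)
  structure(list(cell_id = cid, hap = list(A = ha$seq, B = hb$seq),
                 events = events,
                 phase = phase[, c("class", "chrom", "pos", "hap")],
                 ref_placeholder = ref),
            class = "hap_genome")
}

# Invert a cell's edits to recover the reference sequence needed by the
# deletion-junction check. Substitution classes leave coordinates intact, so
# either haplotype works after mapping; for indels we undo hapA's events.
reconstruct_reference <- function(ha, hb, events, prof, cls) {
  seqs <- ha$seq
  if (cls == "indel") {
    for (cn in names(seqs)) {
      ev <- events$A[[cn]]
      if (nrow(ev) == 0L) next
      s <- seqs[[cn]]
      # undo descending so earlier coordinates stay valid
      ev <- ev[order(ev$pos, decreasing = TRUE), , drop = FALSE]
      for (k in seq_len(nrow(ev))) {
        hpos <- map_ref_to_hap(events$A[[cn]], ev$pos[k])
        if (ev$kind[k] == "INS") {
          s <- paste0(substring(s, 1L, hpos),
                      substring(s, hpos + ev$length[k] + 1L, nchar(s)))
        } else {
          # deleted bases are absent from hapA; recover them from hapB when
          # the deletion is single-haplotype, else from the profile seq (DEL
          # rows carry no seq, so HOM deletions restore placeholder Ns --
          # the junction check never reads inside its own deleted span, and
          # downstream bases come from outside any variant interval)
          key_hap <- map_ref_to_hap(events$B[[cn]], ev$pos[k])
          fill <- if (!is.na(key_hap))
            substring(hb$seq[[cn]], key_hap, key_hap + ev$length[k] - 1L)
          else strrep("N", ev$length[k])
          junction <- if (ev$pos[k] > 1L)
            map_ref_to_hap(events$A[[cn]], ev$pos[k] - 1L) else 0L
          s <- paste0(substring(s, 1L, junction), fill,
                      substring(s, junction + 1L, nchar(s)))
        }
      }
      seqs[[cn]] <- s
    }
  }
  ref_genome_noval(seqs)
}

# internal ref_genome constructor skipping alphabet validation (placeholder
# Ns from HOM-deletion reconstruction are legal anyway, but this also skips
# the O(n) scans on multi-megabase strings in verification loops)
ref_genome_noval <- function(seqs) {
  structure(list(seq = seqs), class = "ref_genome")
}
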