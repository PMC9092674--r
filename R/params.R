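#' Simulation parameters
#'
#' Constructs the single configuration object consumed by every simulator in
#' the package. All downstream functions (`simulate_snp_profiles()`,
#' `simulate_snv_profiles()`, `simulate_indel_profiles()`, the CNV simulator,
#' the genome builder and the read simulator) read their tunables from this
#' object, so one call to `sim_params()` fully specifies a simulated batch.
#'
#' @param ref_path path to the reference FASTA (may be `NULL` until a pipeline
#'   run needs it).
#' @param snp_db_path optional path to a SNP database TSV (see
#'   [parse_dbsnp_table()] for the dialect).
#' @param out_dir output directory for pipeline runs.
#' @param cell_no number of cells per batch.
#' @param snp_no,snv_no,indel_no variants per cell, per class.
#' @param shared_snp_frac fraction of each cell's SNPs drawn from a batch-wide
#'   shared core (default 0.80, so 80\% of SNP sites recur in every cell).
#' @param het_rate probability that a variant is heterozygous (vs homozygous).
#' @param cluster_no number of tumor subclones (0 means an all-normal batch).
#' @param seg_no copy-number segments per chromosome.
#' @param normal_frac fraction of cells that are normal (diploid everywhere);
#'   the normal cell count is `round(normal_frac * cell_no)`, half away from
#'   zero.
#' @param noise_rate per-entry probability that a CNV matrix value is
#'   perturbed by one copy in the noisy matrix.
#' @param p_neutral per-segment probability that a subclone is copy-neutral
#'   (CN = 2) in that segment.
#' @param bin_len CNV bin width in bp.
#' @param max_cn copy-number ceiling (must be at least 3 so a gain state
#'   exists).
#' @param coverage mean sequencing depth attained in a CN = 2 region.
#' @param read_len read length in bp.
#' @param layout `"SE"` or `"PE"`.
#' @param insert_mean,insert_sd paired-end fragment length model (normal,
#'   truncated below at `2 * read_len`).
#' @param error_rate per-base substitution sequencing-error probability.
#' @param base_quality constant Phred score written to FASTQ quality strings.
#' @param seed non-negative integer master seed; every random draw in the
#'   package descends deterministically from it.
#'
#' @return An object of class `sim_params` (a named list).
#' @seealso [validate_params()], [load_params()]
#' @export
sim_params <- function(ref_path = NULL,
                       snp_db_path = NULL,
                       out_dir = ".",
                       cell_no = 10L,
                       snp_no = 1000L,
                       snv_no = 1000L,
                       indel_no = 100L,
                       shared_snp_frac = 0.80,
                       het_rate = 0.5,
                       cluster_no = 4L,
                       seg_no = 7L,
                       normal_frac = 0.2,
                       noise_rate = 0.1,
                       p_neutral = 0.5,
                       bin_len = 500000L,
                       max_cn = 8L,
                       coverage = 5,
                       read_len = 100L,
                       layout = "SE",
                       insert_mean = 300,
                       insert_sd = 30,
                       error_rate = 0.002,
                       base_quality = 30L,
                       seed = 1L) {
  p <- list(
    ref_path = ref_path, snp_db_path = snp_db_path, out_dir = out_dir,
    cell_no = as.integer(cell_no), snp_no = as.integer(snp_no),
    snv_no = as.integer(snv_no), indel_no = as.integer(indel_no),
    shared_snp_frac = as.numeric(shared_snp_frac),
    het_rate = as.numeric(het_rate),
    cluster_no = as.integer(cluster_no), seg_no = as.integer(seg_no),
    normal_frac = as.numeric(normal_frac),
    noise_rate = as.numeric(noise_rate),
    p_neutral = as.numeric(p_neutral),
    bin_len = as.integer(bin_len), max_cn = as.integer(max_cn),
    coverage = as.numeric(coverage), read_len = as.integer(read_len),
    layout = as.character(layout),
    insert_mean = as.numeric(insert_mean), insert_sd = as.numeric(insert_sd),
    error_rate = as.numeric(error_rate),
    base_quality = as.integer(base_quality), seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  p
}

#' Validate a simulation-parameter object
#'
#' Checks every structural invariant of a [sim_params()] object and returns it
#' unchanged when all hold. Each violated invariant raises its own error
#' naming the offending field, so configuration mistakes are reported at the
#' source rather than deep inside a simulator. Idempotent and side-effect
#' free.
#'
#' The feasibility rule links three fields: when `cluster_no > 0`, the batch
#' must be able to give every tumor subclone at least one cell, i.e.
#' `round(normal_frac * cell_no) + cluster_no <= cell_no`.
#'
#' @param p a `sim_params` object.
#' @return `p`, unchanged.
#' @export
validate_params <- function(p) {
  if (!inherits(p, "sim_params")) stop("not a sim_params object")
  chk_int <- function(field, min) {
    v <- p[[field]]
    if (length(v) != 1L || is.na(v) || v < min)
      stop(sprintf("invalid %s: must be an integer >= %d", field, min),
           call. = FALSE)
  }
  chk_frac <- function(field) {
    v <- p[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid %s: must lie in [0, 1]", field), call. = FALSE)
  }
  chk_int("cell_no", 1L)
  chk_int("snp_no", 0L)
  chk_int("snv_no", 0L)
  chk_int("indel_no", 0L)
  chk_int("cluster_no", 0L)
  chk_int("seg_no", 1L)
  chk_int("bin_len", 1L)
  chk_int("read_len", 1L)
  chk_int("base_quality", 0L)
  chk_int("seed", 0L)
  for (f in c("shared_snp_frac", "het_rate", "normal_frac", "noise_rate",
              "p_neutral", "error_rate"))
    chk_frac(f)
  if (p$p_neutral >= 1)
    stop("invalid p_neutral: must be < 1 so aberrant segments exist",
         call. = FALSE)
  if (!is.finite(p$coverage) || p$coverage <= 0)
    stop("invalid coverage: must be a positive real", call. = FALSE)
  if (p$bin_len < p$read_len)
    stop("invalid bin_len: must be >= read_len", call. = FALSE)
  if (p$max_cn < 3L)
    stop("invalid max_cn: must be >= 3 to admit a gain state", call. = FALSE)
  if (!p$layout %in% c("SE", "PE"))
    stop("invalid layout: must be \"SE\" or \"PE\"", call. = FALSE)
  if (!is.finite(p$insert_mean) || p$insert_mean <= 0 ||
      !is.finite(p$insert_sd) || p$insert_sd <= 0)
    stop("invalid insert_mean/insert_sd: must be positive", call. = FALSE)
  if (p$cluster_no > 0L) {
    n_normal <- round_half_up(p$normal_frac * p$cell_no)
    if (n_normal + p$cluster_no > p$cell_no)
      stop(sprintf(
        "infeasible clusters: %d tumor cells cannot host %d clusters (cell_no=%d, normal_frac=%g)",
        p$cell_no - n_normal, p$cluster_no, p$cell_no, p$normal_frac),
        call. = FALSE)
  }
  p
}

#' Load simulation parameters from a flat config file
#'
#' The config format is a flat `key: value` mapping (a YAML-compatible
#' subset): one `key: value` pair per line, `#` starts a comment, blank lines
#' are ignored. Every key is a [sim_params()] argument name; unknown keys are
#' rejected and missing keys take the package defaults. The resulting object
#' is passed through [validate_params()].
#'
#' @param path path to the config file.
#' @return a validated `sim_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  defaults <- sim_params()
  lines <- readLines(path, warn = FALSE)
  overrides <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0)
      stop(sprintf("config parse error at line %d: expected 'key: value'", i),
           call. = FALSE)
    key <- trimws(substr(line, 1L, m - 1L))
    val <- trimws(substr(line, m + 1L, nchar(line)))
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key at line %d: '%s'", i, key),
           call. = FALSE)
    proto <- defaults[[key]]
    parsed <- if (is.null(proto) || is.character(proto)) {
      val
    } else if (is.integer(proto)) {
      iv <- suppressWarnings(as.integer(val))
      if (is.na(iv))
        stop(sprintf("config parse error at line %d: '%s' needs an integer",
                     i, key), call. = FALSE)
      iv
    } else {
      nv <- suppressWarnings(as.numeric(val))
      if (is.na(nv))
        stop(sprintf("config parse error at line %d: '%s' needs a number",
                     i, key), call. = FALSE)
      nv
    }
    overrides[[key]] <- parsed
  }
  p <- defaults
  for (key in names(overrides)) p[[key]] <- overrides[[key]]
  validate_params(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-16s %s\n", f, if (is.null(v)) "<unset>" else format(v)))
  }
  invisible(x)
}

# round half away from zero; base round() goes half-to-even
round_half_up <- function(x) floor(x + 0.5)
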