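# Hierarchical, name-keyed random streams.
#
# One master seed drives the whole simulation. Every simulator stage derives
# an independent child seed from (master seed, stage name, cell index) with a
# small string hash, so adding cells or enabling a later stage never
# reshuffles the draws of earlier cells or stages.

#' Derive a deterministic child seed
#'
#' Hashes the master seed together with any number of string/integer labels
#' (typically a stage name and a cell index) into a seed in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (non-negative integer).
#' @param ... labels; coerced to character and concatenated.
#' @return an integer usable with `set.seed()`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  bytes <- utf8ToInt(key)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps products exact in doubles
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate expr under a given seed, restoring the caller's RNG state after.
with_stream <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
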