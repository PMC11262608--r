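#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state,
#' so that schedule building and simulation are reproducible without
#' clobbering the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# derive a trial-level substream seed from a session seed, kept below 2^31
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + index * 104729) %% 2147483647
}
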