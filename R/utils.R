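## Internal helpers shared across modules.

#' Run an expression under a fixed RNG seed, restoring global RNG state
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed for a pipeline stage
#'
#' All randomness in the synthetic-data module flows from one root seed.
#' Each stage (and each replicate within a stage) draws its own child seed
#' through this deterministic splitting scheme, so any stage can be re-run
#' in isolation and reproduce its share of the stream.
#'
#' @param seed Root integer seed.
#' @param index Stage or replicate index (1-based).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), all(index >= 1))
  m <- .Machine$integer.max  # 2^31 - 1
  as.integer((abs(seed) + 1000003 * as.numeric(index)) %% m)
}

## significance stars used throughout (two-sided p-values)
#' Map p-values to significance stars
#'
#' `p < 0.05` gives `*`, `p < 0.01` gives `**`, `p < 0.001` gives `***`,
#' anything else `ns`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of the same length.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}

## stop() with call.=FALSE everywhere; keep error text grep-able in tests
abort <- function(...) stop(..., call. = FALSE)
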