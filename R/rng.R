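#' Counter-based seed splitting
#'
#' Derives an independent child seed from a master seed and a set of string
#' or integer keys, so that every (dyad, condition, channel, purpose) draw in
#' the synthetic generator has its own reproducible stream. Adding a new
#' purpose (e.g. artifact injection) therefore never perturbs existing draws.
#'
#' The hash is a small splitmix-style integer mix over the UTF-8 bytes of the
#' concatenated keys, reduced modulo 2^31 - 1 so the result is always a valid
#' positive R integer seed.
#'
#' @param seed master integer seed
#' @param ... keys (coerced to character) identifying the stream
#' @return a positive integer seed
#' @keywords internal
derive_seed <- function(seed, ...) {
  keys <- paste(c(seed, ...), collapse = "\x1f")
  bytes <- as.integer(charToRaw(keys))
  h <- 2166136261
  m <- 2^31 - 1
  for (b in bytes) {
    h <- (h * 16777619) %% m
    h <- bitwXor(as.integer(h), as.integer((b * 2654435761) %% m)) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

#' Evaluate an expression under a local RNG stream
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's RNG state.
#'
#' @param seed integer seed for the local stream
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
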