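# Randomness contract: identical (config, seed) must reproduce identical
# output bit-for-bit, and replicate samples must draw from independent,
# deterministically derived substreams.

#' Derive a per-sample seed from a master seed
#'
#' Deterministically maps `(seed, index)` to a new seed below 2^31 so that
#' replicate samples of an experiment use independent RNG substreams while
#' the whole experiment remains reproducible from one master seed.
#'
#' @param seed Master seed (single integer-valued number).
#' @param index Sample index (non-negative integer, vectorised).
#' @return Integer vector of derived seeds.
#' @examples
#' derive_seed(42, 1:3)
#' @export
derive_seed <- function(seed, index) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  s <- (abs(seed) %% m)
  # two multiplicative mixes keep nearby (seed, index) pairs well separated
  as.integer((s * 48271 + (index %% m) * 16807 + 1) %% m)
}

# Set the RNG only when a seed is supplied; NULL leaves the ambient stream
# untouched so callers can manage their own state.
.seed_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
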