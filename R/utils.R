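#' Derive a reproducible child seed from a top-level seed
#'
#' Experiments and ensemble generators consume one user-facing seed and hand
#' each pattern (or each internal random stream) its own derived seed, so
#' ensembles are reproducible member-by-member. The derivation is a fixed
#' affine map modulo the Mersenne prime 2^31 - 1, keeping every derived seed
#' a valid 32-bit integer.
#'
#' @param seed integer top-level seed.
#' @param k integer stream/pattern index (k >= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k), length(k) == 1)
  m <- 2147483647
  s <- ((abs(seed) %% m) * 69069 + k * 104729 + 12345) %% m
  as.integer(if (s == 0) 1 else s)
}

# population-moment normalization used throughout: mean 0, mean square 1
norm01 <- function(x) {
  x <- x - mean(x)
  v <- mean(x * x)
  if (v <= 0) stop("degenerate image: raster is constant, cannot normalize")
  x / sqrt(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
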