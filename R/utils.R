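# Internal helpers: unitary FFTs, seeded RNG substreams, small validators.

# Unitary (orthonormal) 2D DFT. With this convention the forward and inverse
# transforms both carry a 1/sqrt(N*M) factor, so Parseval holds with constant 1
# and k-space noise sd equals image-domain noise sd.
fft2u <- function(x) stats::fft(x) / sqrt(length(x))

ifft2u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
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

# Deterministic substream seed derived from a master seed and a stream index;
# kept inside the 32-bit signed integer range.
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
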