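# Forward encoding model: g_i = S F (A_i * f_i) + n, with a unitary 2D DFT F,
# a per-echo unit-modulus phase map A_i, and a row (phase-encode line) sampling
# operator S shared across echoes.

#' Encode magnitude images into sampled k-space
#'
#' Applies the acquisition model per echo: multiply the magnitude image by its
#' phase map, take the unitary 2D discrete Fourier transform, and zero the
#' phase-encode lines excluded by the sampling mask.
#'
#' @param f An [image_series()].
#' @param A A [phase_map()] with matching dimensions.
#' @param mask Logical vector over phase-encode lines (rows); default full
#'   sampling.
#' @return A [kspace_series()].
#' @export
encode <- function(f, A, mask = NULL) {
  stopifnot(inherits(f, "image_series"), inherits(A, "phase_map"))
  if (!identical(dim(f$data), dim(A$data)))
    stop("image and phase map dimensions differ", call. = FALSE)
  d <- dim(f$data)
  if (is.null(mask)) mask <- rep(TRUE, d[1L])
  if (length(mask) != d[1L])
    stop("mask length must equal the number of phase-encode lines", call. = FALSE)
  mask <- as.logical(mask)
  g <- array(0i, d)
  for (i in seq_len(d[3L])) {
    gi <- fft2u(A$data[, , i] * f$data[, , i])
    gi[!mask, ] <- 0i
    g[, , i] <- gi
  }
  kspace_series(g, f$te, mask)
}

#' Estimate per-echo phase maps from measured k-space
#'
#' The phase of each echo is taken from its zero-filled inverse transform:
#' A_i(x) = exp(i * arg(IFFT(g_i)(x))). Pixels with zero magnitude get phase 1.
#' The estimate is computed once from the data and held fixed by the joint
#' solver.
#'
#' @param g A [kspace_series()].
#' @return A [phase_map()].
#' @export
estimate_phase <- function(g) {
  stopifnot(inherits(g, "kspace_series"))
  d <- dim(g$data)
  A <- array(1 + 0i, d)
  for (i in seq_len(d[3L])) {
    img <- ifft2u(g$data[, , i])
    m <- Mod(img)
    ph <- img
    nz <- m > 0
    ph[nz] <- img[nz] / m[nz]
    ph[!nz] <- 1 + 0i
    A[, , i] <- ph
  }
  phase_map(A)
}

#' Mono-exponential T2 signal decay
#'
#' Propagates the first-echo image along the echo-time ladder:
#' f(x, TE_i) = f(x, TE_0) * exp(-(TE_i - TE_0) / T2(x)). Pixels may have
#' infinite T2 (no decay); nonpositive T2 is an error.
#'
#' @param f0 Numeric matrix, the magnitude image at the first echo time.
#' @param t2 A [t2_map()] or numeric matrix of T2 values in ms (Inf allowed
#'   for non-decaying background).
#' @param te Echo times in ms; `te[1]` is TE_0.
#' @return An [image_series()] whose first echo equals `f0` exactly.
#' @export
decay_signal <- function(f0, t2, te) {
  if (inherits(t2, "t2_map")) t2 <- t2$data
  stopifnot(is.matrix(f0), is.matrix(t2))
  if (!identical(dim(f0), dim(t2)))
    stop("`f0` and `t2` dimensions differ", call. = FALSE)
  if (any(t2 <= 0)) stop("T2 must be strictly positive everywhere", call. = FALSE)
  if (any(diff(te) <= 0)) stop("`te` must be strictly increasing", call. = FALSE)
  ne <- length(te)
  out <- array(0, c(dim(f0), ne))
  out[, , 1L] <- f0
  for (i in seq_len(ne)[-1L])
    out[, , i] <- f0 * exp(-(te[i] - te[1L]) / t2)
  image_series(out, te)
}

#' Cartesian variable-density line-sampling mask
#'
#' Keeps the central 10% of phase-encode lines and randomly discards a fixed
#' fraction of the remaining lines. Rounding of the central-block size and of
#' the discard count uses round-half-to-even on the product. The central block
#' is centered, with ties broken toward the lower (0-based) line index. The
#' result is deterministic for a fixed seed and the kept-line count does not
#' depend on the seed.
#'
#' @param n_lines Number of phase-encode lines (>= 10).
#' @param discard_fraction Fraction of the peripheral lines to discard, in
#'   `[0, 1)`. The acquisition protocols modeled here use 0, 0.25 or 0.33.
#' @param seed Integer seed for the random line selection.
#' @return Logical vector of length `n_lines`, `TRUE` = sampled.
#' @export
make_mask <- function(n_lines, discard_fraction = 0, seed = 1L) {
  if (n_lines < 10L) stop("`n_lines` must be >= 10", call. = FALSE)
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("`discard_fraction` must be in [0, 1)", call. = FALSE)
  n_central <- round(0.10 * n_lines)
  offset_low <- floor((n_lines - n_central) / 2)
  central <- seq.int(offset_low + 1L, offset_low + n_central)
  periph <- setdiff(seq_len(n_lines), central)
  n_discard <- round(discard_fraction * length(periph))
  mask <- rep(TRUE, n_lines)
  if (n_discard > 0) {
    drop <- with_seed(seed, sample(periph, n_discard))
    mask[drop] <- FALSE
  }
  mask
}
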