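# Shared fixtures: all synthetic, built in code at test time.

TE_FSE <- te_ladder("fse11")

small_phantom <- function(grid = 64L, radius = 3L)
  make_vial_phantom(c(grid, grid), vial_radius = radius)

flat_phase <- function(ny, nx, ne) phase_map(array(1 + 0i, c(ny, nx, ne)))

# Unitary 2D DFT by direct summation -- the independent oracle for encode().
naive_dft2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0i, n, m)
  for (k in 0:(n - 1)) for (l in 0:(m - 1)) {
    s <- 0i
    for (a in 0:(n - 1)) for (b in 0:(m - 1))
      s <- s + x[a + 1, b + 1] * exp(-2i * pi * (k * a / n + l * b / m))
    out[k + 1, l + 1] <- s
  }
  out / sqrt(n * m)
}

# In-support / out-of-support error helpers for paired method comparisons.
support_mse <- function(fit, truth_arr, supp) {
  keep <- array(supp, dim(fit$images$data))
  mean((fit$images$data - truth_arr)[keep]^2)
}

aliasing_energy <- function(fit, supp) {
  keep <- array(!supp, dim(fit$images$data))
  mean((fit$images$data[keep])^2)
}
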