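test_that("encode applies the sampled unitary Fourier model", {
  ny <- 16L; nx <- 16L
  A <- flat_phase(ny, nx, 1L)

  # all-zero image maps to all-zero k-space
  z <- image_series(array(0, c(ny, nx, 1L)), 10)
  expect_equal(max(Mod(encode(z, A)$data)), 0)

  # unit impulse at grid center has constant modulus 1/sqrt(N*M)
  imp <- array(0, c(ny, nx, 1L)); imp[ny / 2, nx / 2, 1L] <- 1
  g <- encode(image_series(imp, 10), A)
  expect_equal(range(Mod(g$data)), rep(1 / sqrt(ny * nx), 2), tolerance = 1e-12)

  # matches the direct-summation DFT oracle on a random image
  set.seed(1)
  f <- array(abs(rnorm(ny * nx)), c(ny, nx, 1L))
  g2 <- encode(image_series(f, 10), A)
  expect_lt(max(Mod(g2$data[, , 1L] - naive_dft2(f[, , 1L]))), 1e-10)

  # unitarity: inverse transform recovers the image
  rec <- Mod(ktemap:::ifft2u(g2$data[, , 1L]))
  expect_lt(max(abs(rec - f[, , 1L])) / max(f), 1e-10)

  # masked lines are exactly zero
  mask <- rep(TRUE, ny); mask[c(2L, 9L)] <- FALSE
  gm <- encode(image_series(f, 10), A, mask)
  expect_true(all(gm$data[!mask, , ] == 0i))
  expect_true(any(Mod(gm$data[mask, , ]) > 0))
})

test_that("encode validates shapes and phase modulus", {
  f <- image_series(array(1, c(8, 8, 2)), c(10, 20))
  A_bad_dim <- flat_phase(8L, 8L, 3L)
  expect_error(encode(f, A_bad_dim), "dimensions differ")
  expect_error(phase_map(array(2 + 0i, c(8, 8, 2))), "unit modulus")
  expect_error(encode(f, flat_phase(8L, 8L, 2L), mask = rep(TRUE, 5)), "mask length")
})

test_that("estimate_phase recovers the acquisition phase where signal exists", {
  ny <- 32L; nx <- 32L
  set.seed(2)
  f <- array(1 + abs(rnorm(ny * nx * 2)), c(ny, nx, 2L)) # strictly positive

  # real non-negative image, flat phase: estimated phase is identically 1
  g <- encode(image_series(f, c(10, 20)), flat_phase(ny, nx, 2L))
  expect_lt(max(Mod(estimate_phase(g)$data - 1)), 1e-12)

  # smooth nonzero phase is recovered wherever f > 0
  yy <- matrix(seq_len(ny) / ny, ny, nx)
  xx <- matrix(seq_len(nx) / nx, ny, nx, byrow = TRUE)
  phi <- exp(1i * (0.8 * xx + 0.5 * yy - 0.3))
  A <- phase_map(array(rep(phi, 2), c(ny, nx, 2L)))
  g2 <- encode(image_series(f, c(10, 20)), A)
  expect_lt(max(Mod(estimate_phase(g2)$data - A$data)), 1e-9)

  # an all-zero echo yields phase 1 without error
  g3 <- kspace_series(array(0i, c(ny, nx, 1L)), 10)
  expect_true(all(estimate_phase(g3)$data == 1 + 0i))
})

test_that("decay_signal follows the mono-exponential model", {
  f0 <- matrix(100, 4, 4)
  t2 <- matrix(50, 4, 4)

  # at TE_0 the output equals f0 exactly
  out <- decay_signal(f0, t2, c(10, 60))
  expect_identical(out$data[, , 1L], f0)
  # one T2 later the signal is f0 * exp(-1)
  expect_equal(out$data[1, 1, 2L], 100 * exp(-1), tolerance = 1e-12)

  # per-vial ratios between consecutive echoes equal exp(-dTE/T2)
  ph <- small_phantom()
  fs <- decay_signal(ph$pd, ph$t2_truth, TE_FSE)
  for (v in c(1L, 7L, 14L)) {
    m <- ph$roi_masks[[v]]
    r <- fs$data[, , 5L][m] / fs$data[, , 4L][m]
    expect_equal(unique(round(r, 12)), round(exp(-11 / ph$t2_values[v]), 12))
  }

  # monotone non-increasing in TE everywhere
  d <- fs$data
  expect_true(all(d[, , -1L] <= d[, , -dim(d)[3L]] + 1e-12))

  expect_error(decay_signal(f0, matrix(-1, 4, 4), c(10, 60)), "positive")
})

test_that("make_mask keeps the central block and counts lines deterministically", {
  # zero discard keeps everything
  expect_true(all(make_mask(256L, 0)))

  # documented rounding: 100 lines -> 10 central, round(0.25 * 90) = 22 removed
  m <- make_mask(100L, 0.25, seed = 3)
  expect_equal(sum(m), 100L - 22L)
  expect_true(all(m[46:55]))

  # identical seeds give identical masks; the kept count is seed-independent
  expect_identical(m, make_mask(100L, 0.25, seed = 3))
  expect_false(identical(m, make_mask(100L, 0.25, seed = 4)))
  for (s in 1:20) {
    ms <- make_mask(64L, 0.33, seed = s)
    expect_true(all(ms[30:35])) # central round(6.4) = 6 lines
    expect_equal(sum(ms), 64L - round(0.33 * 58))
  }

  expect_error(make_mask(5L, 0), ">= 10")
  expect_error(make_mask(100L, 1), "0, 1")
})
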