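make_truth_state <- function(ph, te, g, cfg) {
  f_true <- decay_signal(ph$pd, ph$t2_truth, te)
  st <- admm_init(g, cfg, 0)
  st$f <- f_true$data
  st$v <- f_true$data
  st$t2 <- ph$t2_truth
  st
}

test_that("ground truth is a fixed point of one full sweep on noiseless data", {
  ph <- small_phantom()
  g <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 0))
  cfg <- recon_config(denoiser = "identity", sigma = 0)
  A <- estimate_phase(g)
  st <- make_truth_state(ph, TE_FSE, g, cfg)
  f_ref <- st$f
  for (i in 2:length(TE_FSE)) st$f[, , i] <- update_f_i(st, g, A, i, cfg)
  st$f[, , 1L] <- update_f_0(st, g, A, cfg)
  expect_lt(max(abs(st$f - f_ref)) / max(f_ref), 1e-8)

  # identity denoiser keeps v = f; zero residuals keep multipliers at zero
  st$v <- update_v(st, 0, cfg)
  expect_identical(st$v, st$f)
})

test_that("echo-image update approaches the auxiliary target as rho grows", {
  ph <- small_phantom()
  g <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 0))
  A <- estimate_phase(g)
  cfg_big <- recon_config(rho = 1e8, denoiser = "identity", sigma = 0)
  st <- make_truth_state(ph, TE_FSE, g, cfg_big)
  target <- st$f[, , 3L] * 0 + 7 # arbitrary constant target
  st$v[, , 3L] <- target
  st$t2 <- matrix(100, 64, 64) # decay target = f0 * exp(-dTE/100)
  out <- update_f_i(st, g, A, 3L, cfg_big)
  d <- st$f[, , 1L] * exp(-(TE_FSE[3] - TE_FSE[1]) / 100)
  expect_lt(max(abs(out - (target + d) / 2)), 1e-6) # both penalties, equal rho
})

test_that("quadratic updates are minimizers: random perturbations never improve", {
  set.seed(11)
  ny <- 8L; nx <- 8L; ne <- 3L
  te <- c(10, 30, 60)
  f0 <- matrix(abs(rnorm(ny * nx, 5)) + 2, ny)
  t2 <- matrix(runif(ny * nx, 20, 200), ny)
  # full sampling for the echo update: the subproblem is then real-symmetric
  # and the transform-domain solve is the exact real-constrained minimizer
  g <- encode(decay_signal(f0, t2, te), flat_phase(ny, nx, ne))
  A <- estimate_phase(g)
  cfg <- recon_config(denoiser = "identity", sigma = 0)
  st <- admm_init(g, cfg, 0)
  # shift the optimum away from the truth with random multipliers/auxiliaries
  st$y <- array(rnorm(length(st$y), sd = 0.1), dim(st$y))
  st$z <- array(rnorm(length(st$z), sd = 0.1), dim(st$z))
  st$v <- st$v + array(rnorm(length(st$v), sd = 0.1), dim(st$v))

  obj_i <- function(fi, i) {
    d <- st$f[, , 1L] * exp(-(te[i] - te[1]) / st$t2)
    r <- as.double(g$mask) * ktemap:::fft2u(A$data[, , i] * fi) - g$data[, , i]
    0.5 * sum(Mod(r)^2) + sum(st$y[, , i] * (fi - d)) +
      cfg$rho / 2 * sum((fi - d)^2) + sum(st$z[, , i] * (st$v[, , i] - fi)) +
      cfg$rho / 2 * sum((st$v[, , i] - fi)^2)
  }
  fi_star <- update_f_i(st, g, A, 2L, cfg)
  base <- obj_i(fi_star, 2L)
  worse <- replicate(1000, {
    obj_i(fi_star + matrix(rnorm(ny * nx, sd = 0.01), ny), 2L) >= base - 1e-9
  })
  expect_true(all(worse))

  st$f[, , 2L] <- fi_star
  st$f[, , 3L] <- update_f_i(st, g, A, 3L, cfg)

  # undersampled first-echo update: the conjugate-gradient path solves the
  # real-constrained normal equations for arbitrary data
  g <- encode(decay_signal(f0, t2, te), flat_phase(ny, nx, ne),
              mask = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  obj_0 <- function(f0x) {
    r <- as.double(g$mask) * ktemap:::fft2u(A$data[, , 1L] * f0x) - g$data[, , 1L]
    v <- 0.5 * sum(Mod(r)^2)
    for (i in 2:ne) {
      e <- exp(-(te[i] - te[1]) / st$t2)
      v <- v + sum(st$y[, , i] * (st$f[, , i] - f0x * e)) +
        cfg$rho / 2 * sum((st$f[, , i] - f0x * e)^2)
    }
    v + sum(st$z[, , 1L] * (st$v[, , 1L] - f0x)) +
      cfg$rho / 2 * sum((st$v[, , 1L] - f0x)^2)
  }
  f0_star <- update_f_0(st, g, A, cfg)
  base0 <- obj_0(f0_star)
  worse0 <- replicate(1000, {
    obj_0(f0_star + matrix(rnorm(ny * nx, sd = 0.01), ny)) >= base0 - 1e-9
  })
  expect_true(all(worse0))
})

test_that("single-echo first-image update reduces to the decay-free form", {
  set.seed(12)
  ny <- 16L; nx <- 16L
  f <- matrix(abs(rnorm(ny * nx, 5)), ny)
  g <- encode(image_series(array(f, c(ny, nx, 1L)), 10), flat_phase(ny, nx, 1L))
  A <- estimate_phase(g)
  cfg <- recon_config(denoiser = "identity", sigma = 0)
  st <- list(f = array(f, c(ny, nx, 1L)), t2 = matrix(100, ny, nx),
             v = array(rnorm(ny * nx), c(ny, nx, 1L)),
             y = array(0, c(ny, nx, 1L)),
             z = array(rnorm(ny * nx, sd = 0.1), c(ny, nx, 1L)))
  out <- update_f_0(st, g, A, cfg)
  # decay-free closed form: (S g + F(z + rho v)) / (S + rho), projected
  num <- g$data[, , 1L] + ktemap:::fft2u(st$z[, , 1L] + cfg$rho * st$v[, , 1L])
  ref <- pmax(Re(ktemap:::ifft2u(num / (1 + cfg$rho))), 0)
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("multiplier updates follow the scaled residuals exactly", {
  ny <- 4L; nx <- 4L; te <- c(10, 20)
  cfg <- recon_config(rho = 0.5)
  f <- array(abs(rnorm(ny * nx * 2)) + 1, c(ny, nx, 2L))
  st <- list(f = f, t2 = matrix(80, ny, nx), v = f,
             y = array(0, c(ny, nx, 2L)), z = array(0, c(ny, nx, 2L)))

  # consistent state: zero residuals leave multipliers unchanged
  st$f[, , 2L] <- st$f[, , 1L] * exp(-10 / 80)
  st$v <- st$f
  m <- update_multipliers(st, te, cfg)
  expect_equal(max(abs(m$y)), 0)
  expect_equal(max(abs(m$z)), 0)

  # increment is rho * residual, and additive over repeated updates
  st$v[, , 2L] <- st$f[, , 2L] + 2
  m1 <- update_multipliers(st, te, cfg)
  expect_equal(m1$z[, , 2L], matrix(0.5 * 2, ny, nx))
  st$y <- m1$y; st$z <- m1$z
  m2 <- update_multipliers(st, te, cfg)
  expect_equal(m2$z[, , 2L], matrix(2 * 0.5 * 2, ny, nx))
})

test_that("mrc matches its elementwise definition", {
  set.seed(13)
  a <- array(abs(rnorm(4 * 4 * 2)) + 1, c(4, 4, 2))
  expect_equal(mrc(a, a), 0)
  expect_equal(mrc(1.01 * a, a, floor = 1e-12), 0.01, tolerance = 1e-6)

  b <- a + array(rnorm(length(a), sd = 0.1), dim(a))
  b <- pmax(b, 0)
  fl <- 1e-3 * max(abs(a))
  ref <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    ref <- ref + abs(b[i, j, k] - a[i, j, k]) / (abs(a[i, j, k]) + fl)
  expect_equal(mrc(b, a), ref / length(a), tolerance = 1e-12)
})

test_that("joint reconstruction recovers a noiseless phantom and is deterministic", {
  ph <- small_phantom()
  g <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 0))
  jr <- joint_reconstruct(g, recon_config(denoiser = "identity", sigma = 0,
                                          max_iter = 6))
  rs <- roi_stats(jr$t2, ph$roi_masks, truth = ph$t2_truth)
  expect_lt(max(rs$rel_error), 0.02)
  f_true <- decay_signal(ph$pd, ph$t2_truth, TE_FSE)
  expect_lt(max(abs(jr$images$data - f_true$data)) / max(f_true$data), 0.01)

  # bit-identical rerun
  jr2 <- joint_reconstruct(g, recon_config(denoiser = "identity", sigma = 0,
                                           max_iter = 6))
  expect_identical(jr$images$data, jr2$images$data)
  expect_identical(jr$t2$data, jr2$t2$data)

  # max_iter = 0 returns the initialization with an empty convergence log
  jr0 <- joint_reconstruct(g, recon_config(denoiser = "identity", sigma = 0,
                                           max_iter = 0))
  expect_equal(jr0$iterations, 0L)
  expect_length(jr0$mrc, 0)
  zf <- Mod(ktemap:::ifft2u(g$data[, , 1L]))
  expect_equal(jr0$images$data[, , 1L], zf, tolerance = 1e-12)

  lg <- convergence_log(jr)
  expect_s3_class(lg, "tbl_df")
  expect_equal(nrow(lg), jr$iterations)
})
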