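test_that("the 14-vial phantom carries the calibrated ground truth", {
  ph <- make_vial_phantom(c(256L, 256L))
  expect_length(ph$roi_masks, 14L)
  # ROIs are pairwise disjoint
  total <- Reduce(`+`, lapply(ph$roi_masks, function(m) m * 1L))
  expect_lte(max(total), 1L)
  # constant truth per vial at the calibrated values
  for (v in seq_len(14L))
    expect_equal(unique(ph$t2_truth[ph$roi_masks[[v]]]), ph$t2_values[v])
  expect_equal(ph$t2_values[7L], 82.2)
  # background carries no signal
  expect_true(all(ph$pd[!Reduce(`|`, ph$roi_masks)] == 0))

  single <- make_vial_phantom(c(64L, 64L), t2_values = 100, vial_radius = 5L)
  expect_equal(unique(single$t2_truth[is.finite(single$t2_truth)]), 100)

  expect_error(make_vial_phantom(c(64L, 64L), vial_radius = 12L), "overlap")
})

test_that("simulated acquisitions invert exactly without noise and are seeded", {
  ph <- small_phantom()
  g <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 0))
  fit <- two_step_recon(g, sigma = 0)
  f_true <- decay_signal(ph$pd, ph$t2_truth, TE_FSE)
  expect_lt(max(abs(fit$images$data - f_true$data)), 1e-10)

  acq <- acquisition_config(te = TE_FSE, noise_sd = 1.5, seed = 42)
  g1 <- simulate_acquisition(ph, acq)
  g2 <- simulate_acquisition(ph, acq)
  expect_identical(g1$data, g2$data)
  g3 <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 1.5,
                                                    seed = 43))
  expect_false(identical(g1$data, g3$data))
  # echoes draw from independent substreams
  n1 <- g1$data[, , 1L] - g$data[, , 1L]
  n2 <- g1$data[, , 2L] - g$data[, , 2L]
  expect_false(identical(n1, n2))
  expect_lt(abs(stats::cor(as.vector(Re(n1)), as.vector(Re(n2)))), 0.05)
})

test_that("k-space noise maps to image noise of equal sd under the unitary transform", {
  ph <- small_phantom()
  sds <- vapply(1:10, function(s) {
    g <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 2,
                                                     seed = s))
    g0 <- simulate_acquisition(ph, acquisition_config(te = TE_FSE, noise_sd = 0))
    img_noise <- ktemap:::ifft2u(g$data[, , 1L] - g0$data[, , 1L])
    stats::sd(Re(img_noise))
  }, 0)
  expect_lt(abs(mean(sds) - 2) / 2, 0.05)
})

test_that("phase patterns are unit-modulus and recoverable", {
  ph <- small_phantom()
  for (pp in c("linear", "smooth_random")) {
    acq <- acquisition_config(te = TE_FSE, noise_sd = 0, phase_pattern = pp,
                              seed = 3)
    g <- simulate_acquisition(ph, acq)
    A <- estimate_phase(g)
    expect_lt(max(abs(Mod(A$data) - 1)), 1e-9)
    # recovered phase matches the generated pattern wherever there is signal
    truthA <- ktemap:::make_phase_pattern(ph$grid, TE_FSE, pp, 3L)
    supp <- ph$pd > 0
    expect_lt(max(Mod(A$data[, , 1L][supp] - truthA$data[, , 1L][supp])), 1e-8)
  }
})

test_that("the brain-like phantom exposes three labeled compartments", {
  ph <- make_brain_like_phantom(c(96L, 96L))
  expect_named(ph$roi_masks, c("csf", "gm", "wm"))
  expect_true(all(vapply(ph$roi_masks, sum, 0L) > 0L))
  total <- Reduce(`+`, lapply(ph$roi_masks, function(m) m * 1L))
  expect_lte(max(total), 1L)

  flat <- make_brain_like_phantom(c(96L, 96L), t2_csf = 100, t2_gm = 100,
                                  t2_wm = 100)
  expect_equal(unique(flat$t2_truth[flat$pd > 0]), 100)

  expect_error(make_brain_like_phantom(c(32L, 32L)), "at least 64")
})

test_that("a brain-like acquisition is recovered within 5% per compartment", {
  ph <- make_brain_like_phantom(c(96L, 96L))
  te <- te_ladder("grase32")
  g <- simulate_acquisition(ph, acquisition_config(te = te, noise_sd = 1,
                                                   seed = 4))
  jr <- joint_reconstruct(g, recon_config())
  rs <- roi_stats(jr$t2, ph$roi_masks, truth = ph$t2_truth)
  expect_true(all(rs$rel_error < 0.05))
})
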