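# Joint k-space / echo-time ADMM solver.
#
# The model reconstructs all echo images f(x, TE_i) and the T2 map together by
# minimizing sum_i 1/2 |S F A_i f_i - g_i|^2 + R[v_i] subject to the
# mono-exponential decay constraint f_i = f_0 exp(-(TE_i - TE_0)/T2) for i > 0
# and the splitting constraint v_i = f_i. The augmented Lagrangian (penalty
# rho) yields one quadratic subproblem per echo image, a pixelwise weighted
# log-linear fit for T2, a plug-and-play denoising step for v, and gradient
# ascent on the multipliers y_i (decay) and z_i (splitting).

#' Configuration for the joint reconstruction
#'
#' @param rho ADMM penalty parameter (> 0). The default 0.5 is robust across
#'   fully sampled and undersampled data.
#' @param epsilon Relative-change stopping threshold on the images (default
#'   0.01, i.e. 1%).
#' @param max_iter Hard iteration cap (convergence of the plug-and-play
#'   iteration is not guaranteed, so the cap is always enforced).
#' @param check_from_iter First iteration at which the stopping rule is
#'   checked; the mean relative change typically rises before it falls, so
#'   checking starts at iteration 4.
#' @param sigma Optional noise standard deviation override; when `NULL` it is
#'   estimated once from the first-echo zero-filled image.
#' @param conservative_sigma Halve the estimated sigma to preserve detail.
#' @param denoiser Name of a registered plug-and-play denoiser (see
#'   [list_denoisers()]).
#' @param pnp_shift If `TRUE` the denoiser input includes the scaled
#'   splitting multiplier, `f + z/rho`, as the augmented Lagrangian implies;
#'   the default `FALSE` denoises `f` directly (the plug-and-play shortcut).
#' @param t2_clamp Allowed T2 range in ms.
#' @param seed Integer seed for any stochastic component.
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(rho = 0.5, epsilon = 0.01, max_iter = 50L,
                         check_from_iter = 4L, sigma = NULL,
                         conservative_sigma = FALSE, denoiser = "nlm",
                         pnp_shift = FALSE, t2_clamp = c(1, 5000), seed = 1L) {
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 1) stop("`epsilon` must be in (0, 1)", call. = FALSE)
  if (check_from_iter < 1L) stop("`check_from_iter` must be >= 1", call. = FALSE)
  if (max_iter < 0L) stop("`max_iter` must be >= 0", call. = FALSE)
  if (t2_clamp[1L] <= 0 || t2_clamp[2L] <= t2_clamp[1L])
    stop("`t2_clamp` must be an increasing positive range", call. = FALSE)
  structure(list(rho = rho, epsilon = epsilon, max_iter = as.integer(max_iter),
                 check_from_iter = as.integer(check_from_iter), sigma = sigma,
                 conservative_sigma = conservative_sigma, denoiser = denoiser,
                 pnp_shift = pnp_shift, t2_clamp = as.double(t2_clamp),
                 seed = as.integer(seed)),
            class = "recon_config")
}

#' Initialize the ADMM state from measured k-space
#'
#' Images start from the zero-filled inverse-transform magnitudes, the T2 map
#' from a weighted fit of that initialization, the auxiliary images from the
#' images themselves, and the multipliers from zero.
#'
#' @param g A [kspace_series()].
#' @param cfg A [recon_config()].
#' @param sigma Noise sd used by the T2 fit (estimate it first).
#' @return A list of class `admm_state` with fields `f`, `t2`, `v`, `y`, `z`,
#'   `k`, `mrc_history`.
#' @export
admm_init <- function(g, cfg = recon_config(), sigma = 0) {
  d <- dim(g$data)
  f <- array(0, d)
  for (i in seq_len(d[3L])) f[, , i] <- Mod(ifft2u(g$data[, , i]))
  t2 <- fit_t2_wls(image_series(f, g$te), sigma, cfg$t2_clamp)
  structure(list(f = f, t2 = t2$data, v = f,
                 y = array(0, d), z = array(0, d),
                 k = 0L, mrc_history = numeric(0)),
            class = "admm_state")
}

#' Echo-image update for echoes after the first (ADMM step 1)
#'
#' Exact minimizer of the quadratic subproblem for f(x, TE_i), i > 0: the
#' data-fidelity term plus the decay-constraint and splitting penalty terms.
#' After the unit-modulus phase change of variables the normal equations are
#' diagonal in k-space with per-line denominator S + 2 rho, so the solve is a
#' pair of unitary transforms. The result is projected to a magnitude image
#' (real part, negatives clipped).
#'
#' @param state An `admm_state`.
#' @param g Measured [kspace_series()].
#' @param A Fixed [phase_map()].
#' @param i Echo index, 2-based in R (the first echo is TE_0).
#' @param cfg A [recon_config()].
#' @return Updated image matrix for echo `i`.
#' @export
update_f_i <- function(state, g, A, i, cfg) {
  if (i < 2L) stop("`i` must be an echo after the first (i >= 2)", call. = FALSE)
  rho <- cfg$rho
  e <- exp(-(g$te[i] - g$te[1L]) / state$t2)
  d_target <- state$f[, , 1L] * e
  rhs_img <- rho * d_target - state$y[, , i] + state$z[, , i] + rho * state$v[, , i]
  num <- g$data[, , i] + fft2u(A$data[, , i] * rhs_img)
  denom <- as.double(g$mask) + 2 * rho
  if (any(denom <= 0)) stop("singular normal equations (rho must be > 0)", call. = FALSE)
  h_hat <- num / denom # denom recycles down rows = phase-encode lines
  f_new <- Re(Conj(A$data[, , i]) * ifft2u(h_hat))
  pmax(f_new, 0)
}

#' First-echo image update (ADMM step 2)
#'
#' Exact minimizer of the TE_0 subproblem, in which every later echo
#' back-projects an expected first-echo image through the decay model. The
#' data term is diagonal in k-space while the decay terms are diagonal
#' pixelwise, so under full sampling the solve is elementwise; under
#' undersampling the symmetric positive-definite normal equations are solved
#' by conjugate gradients to relative tolerance 1e-12.
#'
#' @inheritParams update_f_i
#' @return Updated image matrix for the first echo.
#' @export
update_f_0 <- function(state, g, A, cfg) {
  rho <- cfg$rho
  ne <- dim(g$data)[3L]
  A0 <- A$data[, , 1L]
  b <- Re(Conj(A0) * ifft2u(g$data[, , 1L])) + state$z[, , 1L] + rho * state$v[, , 1L]
  s2 <- matrix(rho, nrow(b), ncol(b)) # splitting penalty
  if (ne > 1L) {
    for (i in 2:ne) {
      e <- exp(-(g$te[i] - g$te[1L]) / state$t2)
      b <- b + e * (rho * state$f[, , i] + state$y[, , i])
      s2 <- s2 + rho * e * e
    }
  }
  if (all(g$mask)) {
    f_new <- b / (1 + s2)
  } else {
    m <- as.double(g$mask)
    op <- function(x) Re(Conj(A0) * ifft2u(m * fft2u(A0 * x))) + s2 * x
    f_new <- cg_solve(op, b, x0 = state$f[, , 1L], tol = 1e-12, max_iter = 400L)
  }
  pmax(f_new, 0)
}

# Conjugate gradients for a symmetric positive-definite operator on matrices.
cg_solve <- function(op, b, x0, tol = 1e-12, max_iter = 400L) {
  x <- x0
  r <- b - op(x)
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(b * 0)
  for (it in seq_len(max_iter)) {
    if (sqrt(rs) <= tol * bnorm) break
    Ap <- op(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' Pixelwise weighted log-linear T2 fit
#'
#' Fits log f(x, TE_i) - log f(x, TE_0) = -(TE_i - TE_0)/T2(x) by weighted
#' least squares through the origin. The weight of each echo is inversely
#' proportional to the first-order log-domain uncertainty of its decay-rate
#' estimate: w_i is proportional to (TE_i - TE_0) / log((f_i + sigma) /
#' (f_i - sigma)), normalized to sum to one per pixel. In the sigma -> 0
#' limit this reduces to w_i proportional to (TE_i - TE_0) * f_i, which is
#' what is used when `sigma = 0`. The first-order uncertainty is only valid
#' at decent SNR (the same condition under which magnitude noise is
#' approximately Gaussian), so echoes with f_i <= 3 sigma carry zero weight;
#' pixels with no echo above that cut are fitted unweighted. Signals are floored at
#' 1e-6 * max(f_0) before the logarithm; pixels whose echoes all sit at the
#' floor are flagged and set to the clamp maximum, as are non-decaying
#' pixels (non-positive fitted rate).
#'
#' @param f An [image_series()] with at least 2 echoes.
#' @param sigma Noise standard deviation used in the uncertainty weights.
#' @param clamp Allowed T2 range `(min_ms, max_ms)`.
#' @return A [t2_map()] (field `flagged` marks degenerate pixels).
#' @export
fit_t2_wls <- function(f, sigma = 0, clamp = c(1, 5000)) {
  stopifnot(inherits(f, "image_series"))
  ne <- n_echoes(f)
  if (ne < 2L) stop("T2 fitting requires at least 2 echoes", call. = FALSE)
  d <- grid_dim(f)
  npx <- prod(d)
  fm <- matrix(f$data, npx, ne)
  x <- f$te[-1L] - f$te[1L] # (ne-1) echo-time offsets
  floor_val <- 1e-6 * max(fm[, 1L])
  if (floor_val == 0) floor_val <- 1e-12
  fp <- pmax(fm, floor_val)
  ylog <- log(fp[, -1L, drop = FALSE]) - log(fp[, 1L])

  w <- wls_weights(fm[, -1L, drop = FALSE], x, sigma)
  xw <- sweep(w, 2L, x, `*`)
  beta <- -rowSums(xw * ylog) / rowSums(xw * rep(x, each = npx)) # slope 1/T2

  t2 <- ifelse(beta > 0, 1 / beta, clamp[2L])
  t2 <- pmin(pmax(t2, clamp[1L]), clamp[2L])
  if (sigma > 0) {
    # No echo above the noise cut: the pixel carries no reliable signal, so
    # its decay target is relaxed to zero (clamp minimum) rather than
    # exporting an arbitrary long T2 into the decay constraint.
    no_signal <- rowSums(fm[, -1L, drop = FALSE] > 3 * sigma) == 0L
    t2[no_signal] <- clamp[1L]
  }
  flagged <- rowSums(fm > floor_val) == 0L
  t2[flagged] <- clamp[2L]
  t2_map(matrix(t2, d[1L], d[2L]), clamp = clamp,
         flagged = matrix(flagged, d[1L], d[2L]))
}

# Per-pixel normalized weights for the log-linear fit (npx x (ne-1)).
wls_weights <- function(fi, x, sigma) {
  npx <- nrow(fi)
  if (sigma <= 0) {
    w <- sweep(fi, 2L, x, `*`)
    w[w <= 0] <- .Machine$double.eps
  } else {
    # w_i = x_i / log((f_i + sigma)/(f_i - sigma)). The first-order log-domain
    # uncertainty behind this weight (like the Gaussian approximation of the
    # magnitude noise) holds only at SNR > 3; below that the weight is
    # unreliable (it otherwise rewards late pure-noise echoes through the
    # TE-offset factor), so the echo train is truncated at the noise floor:
    # the true decay is monotone, so once an echo falls to 3*sigma every
    # later echo is dropped too, spikes included. Pixels with no echo above
    # the cut fall back to an unweighted fit.
    valid <- fi > 3 * sigma
    if (ncol(valid) > 1L)
      for (j in 2:ncol(valid)) valid[, j] <- valid[, j] & valid[, j - 1L]
    w <- matrix(0, npx, ncol(fi))
    w[valid] <- (rep(x, each = npx)[valid]) /
      log((fi[valid] + sigma) / (fi[valid] - sigma))
    none <- rowSums(valid) == 0L
    w[none, ] <- 1
  }
  w / rowSums(w)
}

#' Auxiliary-image (denoising) update (ADMM step 3)
#'
#' Applies the plug-and-play denoiser to each echo image. By default the
#' denoiser input is the current image itself; with `cfg$pnp_shift = TRUE`
#' the scaled splitting multiplier is added first (`f + z/rho`), as the
#' augmented Lagrangian implies.
#'
#' @inheritParams update_f_i
#' @param sigma Noise standard deviation passed to the denoiser.
#' @return Updated auxiliary image array.
#' @export
update_v <- function(state, sigma, cfg) {
  denoise <- get_denoiser(cfg$denoiser)
  v <- state$f
  if (cfg$pnp_shift) v <- v - state$z / cfg$rho
  for (i in seq_len(dim(v)[3L])) v[, , i] <- denoise(v[, , i], sigma)
  v
}

#' Multiplier updates (ADMM steps 4-5)
#'
#' Gradient ascent on the two sets of multipliers: y_i grows with the decay
#' residual f_i - f_0 exp(-(TE_i - TE_0)/T2) (echoes after the first) and z_i
#' with the splitting residual v_i - f_i (every echo), each scaled by rho.
#'
#' @inheritParams update_f_i
#' @param te Echo times in ms.
#' @return List with updated `y` and `z` arrays.
#' @export
update_multipliers <- function(state, te, cfg) {
  rho <- cfg$rho
  y <- state$y
  z <- state$z
  ne <- length(te)
  if (ne > 1L) {
    for (i in 2:ne) {
      e <- exp(-(te[i] - te[1L]) / state$t2)
      y[, , i] <- y[, , i] + rho * (state$f[, , i] - state$f[, , 1L] * e)
    }
  }
  for (i in seq_len(ne))
    z[, , i] <- z[, , i] + rho * (state$v[, , i] - state$f[, , i])
  list(y = y, z = z)
}

#' Mean relative intensity change between successive iterates
#'
#' Mean over foreground pixels and echoes of
#' `|f_new - f_old| / (|f_old| + floor)`; the floor (default 1e-3 of the peak
#' old intensity) guards the division in empty regions.
#'
#' @param f_new,f_old Image arrays or [image_series()] of matching shape.
#' @param foreground Optional logical matrix restricting the mean (default:
#'   all pixels).
#' @param floor Denominator floor; default `1e-3 * max(f_old)`.
#' @return Non-negative scalar.
#' @export
mrc <- function(f_new, f_old, foreground = NULL, floor = NULL) {
  if (inherits(f_new, "image_series")) f_new <- f_new$data
  if (inherits(f_old, "image_series")) f_old <- f_old$data
  if (!identical(dim(f_new), dim(f_old)))
    stop("`f_new` and `f_old` shapes differ", call. = FALSE)
  if (is.null(floor)) floor <- 1e-3 * max(abs(f_old))
  if (floor <= 0) floor <- .Machine$double.eps
  rel <- abs(f_new - f_old) / (abs(f_old) + floor)
  if (!is.null(foreground)) {
    keep <- array(as.logical(foreground), dim(f_new))
    mean(rel[keep])
  } else {
    mean(rel)
  }
}

#' Joint reconstruction of echo images and T2 map
#'
#' Runs the full ADMM loop: per-echo image updates, first-echo update, the
#' weighted log-linear T2 fit, the plug-and-play denoising step, and the
#' multiplier updates, until the mean relative change of the images falls
#' below `cfg$epsilon` (checked from `cfg$check_from_iter`) or `cfg$max_iter`
#' is reached (with a warning). The phase map is estimated once from the
#' measured data and held fixed; the noise level is estimated once from the
#' first-echo zero-filled image unless `cfg$sigma` overrides it.
#'
#' @param g A [kspace_series()] with at least 2 echoes.
#' @param cfg A [recon_config()].
#' @return A list of class `kte_fit` with fields `images` ([image_series()]),
#'   `t2` ([t2_map()]), `sigma`, `mrc` (per-iteration log), `iterations`,
#'   `converged`, `config`, `method`.
#' @export
joint_reconstruct <- function(g, cfg = recon_config()) {
  stopifnot(inherits(g, "kspace_series"))
  if (n_echoes(g) < 2L)
    stop("joint reconstruction requires at least 2 echoes", call. = FALSE)
  A <- estimate_phase(g)
  est <- NULL
  f0_init <- Mod(ifft2u(g$data[, , 1L]))
  if (is.null(cfg$sigma)) {
    est <- estimate_sigma(f0_init, cfg$conservative_sigma)
    sigma <- est$sigma
    fg <- est$foreground
  } else {
    sigma <- cfg$sigma
    fg <- tryCatch(estimate_sigma(f0_init, FALSE)$foreground,
                   error = function(e) NULL)
  }
  state <- admm_init(g, cfg, sigma)

  converged <- FALSE
  if (cfg$max_iter > 0L) {
    for (k in seq_len(cfg$max_iter)) {
      f_old <- state$f
      for (i in 2:n_echoes(g))
        state$f[, , i] <- update_f_i(state, g, A, i, cfg)
      state$f[, , 1L] <- update_f_0(state, g, A, cfg)
      fit <- fit_t2_wls(image_series(state$f, g$te), sigma, cfg$t2_clamp)
      state$t2 <- fit$data
      state$v <- update_v(state, sigma, cfg)
      mult <- update_multipliers(state, g$te, cfg)
      state$y <- mult$y
      state$z <- mult$z
      if (any(!is.finite(state$f)) || any(!is.finite(state$t2)) ||
          any(!is.finite(state$v)) || any(!is.finite(state$y)) ||
          any(!is.finite(state$z)))
        stop(sprintf("non-finite values produced at iteration %d", k),
             call. = FALSE)
      # Denominator floored at the noise level: intensity changes of pixels
      # below sigma are noise, and on magnitude scanner data the Rician floor
      # keeps |f| above sigma anyway.
      m <- mrc(state$f, f_old, fg,
               floor = max(sigma, 1e-3 * max(abs(f_old))))
      state$k <- k
      state$mrc_history <- c(state$mrc_history, m)
      if (k >= cfg$check_from_iter && m < cfg$epsilon) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning(sprintf("stopping rule not met within max_iter = %d iterations",
                      cfg$max_iter), call. = FALSE)
  }

  final_fit <- fit_t2_wls(image_series(state$f, g$te), sigma, cfg$t2_clamp)
  structure(list(images = image_series(state$f, g$te), t2 = final_fit,
                 sigma = sigma, noise_estimate = est, mrc = state$mrc_history,
                 iterations = state$k, converged = converged, config = cfg,
                 method = "joint"),
            class = "kte_fit")
}

#' @export
print.kte_fit <- function(x, ...) {
  cat(sprintf("<kte_fit:%s> %d echoes on %d x %d, %d iterations%s, sigma = %g\n",
              x$method, n_echoes(x$images), nrow(x$t2$data), ncol(x$t2$data),
              x$iterations,
              if (isTRUE(x$converged)) " (converged)" else "", x$sigma))
  invisible(x)
}

#' Per-iteration convergence log of a fit
#'
#' @param x A `kte_fit`.
#' @param ... Unused.
#' @return A tibble with columns `iteration` and `mrc`.
#' @export
convergence_log <- function(x, ...) {
  stopifnot(inherits(x, "kte_fit"))
  tibble::tibble(iteration = seq_along(x$mrc), mrc = x$mrc)
}
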