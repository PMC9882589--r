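#' Estimate the Gaussian noise standard deviation of a magnitude image
#'
#' The estimate drives both the plug-and-play denoiser strength and the
#' uncertainty weights of the log-linear T2 fit. The background is removed by
#' Otsu's threshold on the intensity histogram; the image is tiled into
#' non-overlapping 5 x 5 patches, patches fully inside the foreground are
#' kept, and the sample standard deviation of each patch is collected. The
#' returned sigma is the mode of these local standard deviations, located as
#' the center of the tallest bin of a Freedman-Diaconis histogram (ties broken
#' toward the smaller value). With `conservative = TRUE` the estimate is
#' halved to preserve more image detail.
#'
#' @param image Non-negative numeric matrix (magnitude image).
#' @param conservative Halve the estimate (`FALSE` by default).
#' @return A list of class `noise_estimate` with fields `sigma`,
#'   `conservative`, `threshold` (the Otsu cut), `n_patches`, and `foreground`
#'   (the logical foreground mask).
#' @export
estimate_sigma <- function(image, conservative = FALSE) {
  stopifnot(is.matrix(image))
  if (min(image) < 0) stop("`image` must be non-negative", call. = FALSE)
  rng <- range(image)
  if (rng[2] > rng[1]) {
    thr <- EBImage::otsu(image, range = rng, levels = 256L)
  } else {
    thr <- rng[1] - 1 # constant image: everything is foreground
  }
  fg <- image > thr
  # Otsu always splits the histogram, even when there is no real background
  # (e.g. a noisy but fully occupied field of view). Accept the split as
  # background removal only if the dim class is substantially darker than
  # the bright class; otherwise keep the whole image as foreground.
  if (any(fg) && any(!fg) && mean(image[!fg]) > 0.5 * mean(image[fg])) {
    thr <- rng[1] - 1
    fg <- image > thr
  }
  sds <- patch_sds(image, fg, 5L)
  if (length(sds) == 0L)
    stop(sprintf("no 5x5 patch lies fully inside the foreground (Otsu threshold = %g)",
                 thr), call. = FALSE)
  sigma <- mode_fd(sds)
  if (conservative) sigma <- 0.5 * sigma
  structure(list(sigma = sigma, conservative = conservative, threshold = thr,
                 n_patches = length(sds), foreground = fg),
            class = "noise_estimate")
}

# Sample sds of non-overlapping size x size patches fully inside `fg`.
patch_sds <- function(image, fg, size = 5L) {
  ny <- nrow(image); nx <- ncol(image)
  out <- numeric(0)
  for (r0 in seq.int(1L, ny - size + 1L, by = size)) {
    for (c0 in seq.int(1L, nx - size + 1L, by = size)) {
      rr <- r0:(r0 + size - 1L); cc <- c0:(c0 + size - 1L)
      if (all(fg[rr, cc])) out <- c(out, stats::sd(image[rr, cc]))
    }
  }
  out
}

# Mode of a continuous sample: center of the tallest Freedman-Diaconis bin.
mode_fd <- function(x) {
  if (length(x) == 1L) return(x)
  iqr <- stats::IQR(x)
  if (iqr == 0 || diff(range(x)) == 0) return(stats::median(x))
  bw <- 2 * iqr / length(x)^(1 / 3)
  breaks <- seq(min(x), max(x) + bw, by = bw)
  h <- hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %g%s (Otsu threshold %g, %d patches)\n",
              x$sigma, if (x$conservative) " [conservative x0.5]" else "",
              x$threshold, x$n_patches))
  invisible(x)
}
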