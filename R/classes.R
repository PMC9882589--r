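#' Multi-echo k-space series
#'
#' Container for the measured spatial-frequency data of a multi-echo
#' acquisition: one complex 2D array per echo time, the echo-time ladder, and
#' the Cartesian line-sampling mask. Phase-encode lines are array rows; a line
#' excluded by the mask is identically zero in the data.
#'
#' @param data Complex array of dimension `ny x nx x n_echo`.
#' @param te Numeric vector of echo times in ms, strictly increasing, one per
#'   echo.
#' @param mask Logical vector of length `ny`, `TRUE` for sampled phase-encode
#'   lines. Integer 0/1 vectors are coerced.
#' @return An object of class `kspace_series` with fields `data`, `te`, `mask`.
#' @export
kspace_series <- function(data, te, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a ny x nx x n_echo array", call. = FALSE)
  if (!is.complex(data)) data <- data + 0i
  d <- dim(data)
  if (length(te) != d[3L])
    stop(sprintf("length(te) [%d] must equal the number of echoes [%d]",
                 length(te), d[3L]), call. = FALSE)
  if (any(diff(te) <= 0)) stop("`te` must be strictly increasing", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, d[1L])
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("integer `mask` must contain only 0/1", call. = FALSE)
    mask <- as.logical(mask)
  }
  if (length(mask) != d[1L])
    stop(sprintf("length(mask) [%d] must equal ny [%d]", length(mask), d[1L]),
         call. = FALSE)
  if (any(abs(data[!mask, , ]) > 0))
    stop("masked-out phase-encode lines must be exactly zero", call. = FALSE)
  structure(list(data = data, te = as.double(te), mask = mask),
            class = "kspace_series")
}

#' Multi-echo magnitude image series
#'
#' Real, non-negative T2-weighted magnitude images on a common grid, one per
#' echo time.
#'
#' @param data Numeric array `ny x nx x n_echo`, all values >= 0.
#' @param te Echo times in ms, strictly increasing.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, te) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a ny x nx x n_echo array", call. = FALSE)
  if (is.complex(data)) stop("`data` must be real", call. = FALSE)
  if (any(!is.finite(data))) stop("`data` must be finite", call. = FALSE)
  if (min(data) < 0) stop("magnitude images must be non-negative", call. = FALSE)
  if (length(te) != dim(data)[3L])
    stop("length(te) must equal the number of echoes", call. = FALSE)
  if (any(diff(te) <= 0)) stop("`te` must be strictly increasing", call. = FALSE)
  structure(list(data = data, te = as.double(te)), class = "image_series")
}

#' Per-echo phase maps
#'
#' Complex unit-modulus phase factors of the acquisition, one 2D map per echo.
#' Every entry must satisfy |A| = 1 (checked to 1e-9).
#'
#' @param data Complex array `ny x nx x n_echo` with unit-modulus entries.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a ny x nx x n_echo array", call. = FALSE)
  if (!is.complex(data)) data <- data + 0i
  if (max(abs(Mod(data) - 1)) > 1e-9)
    stop("phase map entries must have unit modulus (|A| = 1 within 1e-9)",
         call. = FALSE)
  structure(list(data = data), class = "phase_map")
}

#' Pixelwise T2 map
#'
#' Transverse relaxation times in ms. Values must be strictly positive and
#' within the clamp range carried by the object.
#'
#' @param data Numeric matrix of T2 values (ms).
#' @param clamp Length-2 numeric `(min_ms, max_ms)` range the values were
#'   clamped to.
#' @param flagged Optional logical matrix marking pixels where the fit was
#'   degenerate (all echoes at the positivity floor).
#' @return An object of class `t2_map`.
#' @export
t2_map <- function(data, clamp = c(1, 5000), flagged = NULL) {
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  if (any(!is.finite(data)) || min(data) <= 0)
    stop("T2 values must be finite and strictly positive", call. = FALSE)
  if (min(data) < clamp[1L] - 1e-12 || max(data) > clamp[2L] + 1e-12)
    stop("T2 values outside the clamp range", call. = FALSE)
  if (is.null(flagged)) flagged <- matrix(FALSE, nrow(data), ncol(data))
  structure(list(data = data, clamp = as.double(clamp), flagged = flagged),
            class = "t2_map")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_series> %d x %d grid, %d echoes (TE %g..%g ms), %d/%d lines sampled\n",
              d[1], d[2], d[3], min(x$te), max(x$te), sum(x$mask), d[1]))
  invisible(x)
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %d x %d grid, %d echoes (TE %g..%g ms), range [%g, %g]\n",
              d[1], d[2], d[3], min(x$te), max(x$te), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<t2_map> %d x %d, T2 range [%g, %g] ms (clamp [%g, %g]), %d flagged pixels\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data),
              x$clamp[1], x$clamp[2], sum(x$flagged)))
  invisible(x)
}

n_echoes <- function(x) dim(x$data)[3L]

grid_dim <- function(x) dim(x$data)[1:2]
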