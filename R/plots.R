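#' Display a T2 map
#'
#' Simple base-graphics rendering with a fixed intensity window.
#'
#' @param x A [t2_map()].
#' @param zlim Display window in ms (default: the 1st-99th percentile range).
#' @param ... Passed to [graphics::image()].
#' @export
plot.t2_map <- function(x, zlim = NULL, ...) {
  if (is.null(zlim)) zlim <- stats::quantile(x$data, c(0.01, 0.99))
  m <- pmin(pmax(x$data, zlim[1L]), zlim[2L])
  graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(m) / ncol(m), zlim = zlim, ...)
  invisible(x)
}

#' Plot the convergence of a reconstruction
#'
#' Mean relative intensity change per iteration on a log scale, with the
#' stopping threshold of the fit's configuration, if any, as a dashed line.
#'
#' @param x A `kte_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kte_fit <- function(x, ...) {
  if (length(x$mrc) == 0L) {
    warning("no iterations to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::plot(seq_along(x$mrc), x$mrc, type = "b", log = "y",
                 xlab = "iteration", ylab = "mean relative change", ...)
  if (!is.null(x$config))
    graphics::abline(h = x$config$epsilon, lty = 2)
  invisible(x)
}
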