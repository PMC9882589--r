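# ROI-based quantitative evaluation of T2 maps.

#' Per-ROI T2 statistics
#'
#' Mean and standard deviation of the T2 values inside each labeled region,
#' optionally against a ground-truth map. Standard deviations use the sample
#' (n - 1) convention. By default each ROI is eroded by one pixel before the
#' statistics are taken, to keep partial-volume rim pixels of the synthetic
#' phantom out of the summary.
#'
#' @param t2 A [t2_map()] or numeric matrix (ms).
#' @param rois Named list of logical masks (disjoint), or a labeled integer
#'   matrix (0 = background).
#' @param truth Optional ground-truth [t2_map()], numeric matrix, or a named
#'   numeric vector of per-ROI true T2 values.
#' @param erode Erode each ROI by one pixel first (default `TRUE`).
#' @return A tibble with columns `label`, `n`, `mean`, `sd`, and (when truth
#'   is supplied) `truth`, `rel_error`. Empty ROIs are reported absent with a
#'   warning.
#' @export
roi_stats <- function(t2, rois, truth = NULL, erode = TRUE) {
  if (inherits(t2, "t2_map")) t2 <- t2$data
  stopifnot(is.matrix(t2))
  rois <- as_roi_list(rois, dim(t2))
  truth_map <- NULL
  truth_vec <- NULL
  if (!is.null(truth)) {
    if (inherits(truth, "t2_map")) truth <- truth$data
    if (is.matrix(truth)) truth_map <- truth else truth_vec <- truth
  }
  rows <- list()
  for (lab in names(rois)) {
    m <- rois[[lab]]
    if (erode) m <- erode1(m)
    n <- sum(m)
    if (n == 0L) {
      warning(sprintf("ROI '%s' is empty%s and was dropped", lab,
                      if (erode) " after erosion" else ""), call. = FALSE)
      next
    }
    vals <- t2[m]
    row <- tibble::tibble(label = lab, n = n, mean = mean(vals),
                          sd = if (n > 1L) stats::sd(vals) else 0)
    if (!is.null(truth_map)) {
      tv <- mean(truth_map[m][is.finite(truth_map[m])])
      row$truth <- tv
      row$rel_error <- abs(row$mean - tv) / tv
    } else if (!is.null(truth_vec)) {
      tv <- unname(truth_vec[lab])
      row$truth <- tv
      row$rel_error <- abs(row$mean - tv) / tv
    }
    rows[[lab]] <- row
  }
  do.call(rbind, rows)
}

as_roi_list <- function(rois, dm) {
  if (is.matrix(rois) && !is.logical(rois)) {
    labs <- sort(setdiff(unique(as.vector(rois)), 0))
    rois <- stats::setNames(lapply(labs, function(l) rois == l),
                            sprintf("roi%02d", labs))
  }
  stopifnot(is.list(rois))
  if (is.null(names(rois)) || any(names(rois) == ""))
    names(rois) <- sprintf("roi%02d", seq_along(rois))
  for (m in rois) {
    stopifnot(is.logical(m), identical(dim(m), as.integer(dm)) || identical(dim(m), dm))
  }
  rois
}

# One-pixel binary erosion (8-neighborhood box).
erode1 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  out <- m
  for (dy in -1:1) for (dx in -1:1)
    out <- out & pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
  out
}

#' Side-by-side comparison of per-ROI reports
#'
#' Stacks ROI reports from several methods and adds, per ROI, the ratio of
#' each method's standard deviation to the reference method's (a ratio below
#' one means tighter pixelwise T2 values than the reference).
#'
#' @param reports Named list of [roi_stats()] tibbles (names = method labels).
#' @param reference Method name used as the denominator of the sd ratio
#'   (default: the first report).
#' @return A tibble keyed by `label` x `method`, with `sd_ratio` columns.
#' @export
compare_methods <- function(reports, reference = names(reports)[1L]) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop("`reports` must be a named list (method labels)", call. = FALSE)
  labs <- reports[[1L]]$label
  for (r in reports)
    if (!identical(sort(r$label), sort(labs)))
      stop("all reports must share the same ROI labels", call. = FALSE)
  ref <- reports[[reference]]
  out <- list()
  for (mname in names(reports)) {
    r <- reports[[mname]]
    r$method <- mname
    r$sd_ratio <- r$sd / ref$sd[match(r$label, ref$label)]
    out[[mname]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$label, res$method), ]
}
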