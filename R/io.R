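# File formats. K-space series travel in an HDF5 container; magnitude images
# and T2 maps in NIfTI. Precision contract: double/complex-double in memory,
# float32 for NIfTI images on disk; the HDF5 k-space container keeps full
# double precision (real/imaginary stored as separate datasets, since the
# HDF5 bindings carry no complex dtype).

KSPACE_DATASETS <- c("/kspace_real", "/kspace_imag", "/te_ms", "/mask")

#' Write a k-space series to an HDF5 container
#'
#' Schema: `/kspace_real` and `/kspace_imag` (double, ny x nx x n_echo),
#' `/te_ms` (double), `/mask` (integer 0/1 per phase-encode line). The
#' roundtrip through [read_kspace()] is lossless.
#'
#' @param ks A [kspace_series()].
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_kspace <- function(ks, path) {
  stopifnot(inherits(ks, "kspace_series"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(Re(ks$data), path, "kspace_real", native = TRUE)
  rhdf5::h5write(Im(ks$data), path, "kspace_imag", native = TRUE)
  rhdf5::h5write(ks$te, path, "te_ms", native = TRUE)
  rhdf5::h5write(as.integer(ks$mask), path, "mask", native = TRUE)
  invisible(path)
}

#' Read a k-space series from an HDF5 container
#'
#' @param path HDF5 file written by [write_kspace()] (or any file following
#'   the same schema). Missing datasets raise an error naming the dataset;
#'   an integer 0/1 mask is accepted and coerced to logical.
#' @return A [kspace_series()].
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- paste0("/", rhdf5::h5ls(path)$name)
  for (ds in KSPACE_DATASETS)
    if (!ds %in% present)
      stop(sprintf("k-space container is missing dataset %s", ds), call. = FALSE)
  re <- rhdf5::h5read(path, "kspace_real", native = TRUE)
  im <- rhdf5::h5read(path, "kspace_imag", native = TRUE)
  te <- as.double(rhdf5::h5read(path, "te_ms", native = TRUE))
  mask <- as.vector(rhdf5::h5read(path, "mask", native = TRUE))
  if (!identical(dim(re), dim(im)))
    stop("real/imaginary dataset shapes differ", call. = FALSE)
  data <- array(complex(real = re, imaginary = im), dim(re))
  kspace_series(data, te, mask)
}

#' Write images or a T2 map as NIfTI
#'
#' Magnitude image series are stored as 3D volumes with echoes along the
#' third axis; T2 maps as singleton-third-axis volumes. Values are stored in
#' float32 with an identity affine (synthetic-data convention). Non-finite
#' voxels are refused.
#'
#' @param x An [image_series()], [t2_map()], matrix, or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "image_series")) x <- x$data
  if (inherits(x, "t2_map")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (any(!is.finite(x)))
    stop("refusing to write non-finite voxel values", call. = FALSE)
  RNifti::writeNifti(RNifti::asNifti(x, datatype = "float"), path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return A 3D numeric array (echo or singleton third axis).
#' @export
read_image <- function(path) {
  x <- RNifti::readNifti(path)
  x <- as.array(x)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  x
}
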