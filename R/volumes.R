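#' Construct a volumetric image
#'
#' A `brain_volume` is a 3D scalar grid with voxel dimensions and a tag
#' naming the common template space it lives in.  All stages of the
#' pipeline require their inputs on one common grid (same shape, voxel
#' size and space tag); mixed grids are refused rather than resampled.
#'
#' @param data numeric 3D array (T1 in ms, z-scores, or streamline density
#'   depending on role).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param space character tag identifying the template grid.
#' @return an object of class `brain_volume`.
#' @export
brain_volume <- function(data, voxel_size = c(1, 1, 1), space = "template") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive finite numbers")
  structure(list(data = data, voxel_size = voxel_size,
                 space = as.character(space)[1L]),
            class = "brain_volume")
}

#' Construct a binary mask
#'
#' Masks share the grid of the images they are applied to; values are
#' strictly logical.
#'
#' @param data logical (or 0/1 numeric) 3D array.
#' @inheritParams brain_volume
#' @return an object of class `c("brain_mask", "brain_volume")`.
#' @export
brain_mask <- function(data, voxel_size = c(1, 1, 1), space = "template") {
  data <- as.array(data)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be 0/1 or logical")
    data <- array(data > 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask values must be 0/1 or logical")
  v <- brain_volume(data, voxel_size, space)
  class(v) <- c("brain_mask", "brain_volume")
  v
}

#' @export
print.brain_volume <- function(x, ...) {
  kind <- if (inherits(x, "brain_mask")) "brain_mask" else "brain_volume"
  cat(sprintf("<%s> %s, voxel %s mm, space '%s'\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"), x$space))
  vals <- x$data[is.finite(x$data)]
  if (inherits(x, "brain_mask")) {
    cat(sprintf("  %d voxels set (%.3f mL)\n", sum(x$data),
                sum(x$data) * voxel_volume(x) / 1000))
  } else if (length(vals)) {
    cat(sprintf("  finite range [%.4g, %.4g], %d NaN/NA\n",
                min(vals), max(vals), sum(!is.finite(x$data))))
  }
  invisible(x)
}

# extract the bare array from a brain_volume / brain_mask or pass arrays through
vol_data <- function(x) {
  if (inherits(x, "brain_volume")) x$data else as.array(x)
}

#' Voxel volume in cubic millimetres
#'
#' @param x a `brain_volume` or a length-3 numeric of voxel sizes in mm.
#' @return dx*dy*dz in mm^3 (1 mL = 1000 mm^3).
#' @export
voxel_volume <- function(x) {
  vs <- if (inherits(x, "brain_volume")) x$voxel_size else as.numeric(x)
  prod(vs)
}

#' Check that a set of volumes shares one grid
#'
#' Pure predicate: TRUE iff all shapes, voxel sizes (to 1e-6 mm) and space
#' tags agree.  Pipeline stages raise an error when it is FALSE.
#'
#' @param images non-empty list of `brain_volume` / `brain_mask` objects.
#' @return logical scalar.
#' @export
check_same_grid <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    stop("need a non-empty list of volumes")
  ref <- images[[1L]]
  all(vapply(images, function(im) {
    identical(dim(vol_data(im)), dim(vol_data(ref))) &&
      all(abs(im$voxel_size - ref$voxel_size) <= 1e-6) &&
      identical(im$space, ref$space)
  }, logical(1L)))
}

stop_unless_same_grid <- function(..., what = "inputs") {
  if (!check_same_grid(list(...)))
    stop(what, " are not on the same grid (shape/voxel size/space must match)")
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param space space tag to attach (NIfTI has no canonical field for it).
#' @return a `brain_volume`.
#' @export
read_volume <- function(path, space = "template") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D: ", path)
  vs <- RNifti::pixdim(img)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    stop("non-finite or non-positive voxel sizes in header: ", path)
  brain_volume(array(as.numeric(img), dim = d), vs, space)
}

#' Write a volume as NIfTI
#'
#' Data are stored as float64 so that values (including float32 inputs)
#' round-trip bit-exactly.
#'
#' @param vol `brain_volume` or `brain_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  dat <- vol$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim = dim(dat))
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Values must be 0/1; anything else is an error.
#'
#' @inheritParams read_volume
#' @return a `brain_mask`.
#' @export
read_mask <- function(path, space = "template") {
  v <- read_volume(path, space)
  if (!all(v$data %in% c(0, 1)))
    stop("mask file contains values other than 0/1: ", path)
  brain_mask(v$data > 0, v$voxel_size, v$space)
}
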