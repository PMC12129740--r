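#' Define a volume grid
#'
#' A `volume_grid` describes the sampling lattice shared by every volume in a
#' pipeline run: array dimensions, voxel size in mm, and the world-space
#' position of voxel (1,1,1).  All volumes exchanged between pipeline stages
#' must carry the same grid; mismatches raise an error rather than triggering
#' silent resampling (the pipeline never resamples).
#'
#' @param shape integer(3), number of voxels along x, y, z (each >= 1).
#' @param voxel_size_mm numeric(3), voxel edge lengths in mm (each > 0).
#' @param origin numeric(3), world mm coordinate of the first voxel.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(20, 20, 12), c(3, 3, 3))
#' voxel_volume_mm3(g)
#' @export
volume_grid <- function(shape, voxel_size_mm = c(3, 3, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(voxel_size_mm) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape entries must be >= 1")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be > 0")
  structure(list(shape = shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @method print volume_grid
#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s voxels, %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' @rdname volume_grid
#' @export
voxel_volume_mm3 <- function(shape) {
  stopifnot(inherits(shape, "volume_grid"))
  prod(shape$voxel_size_mm)
}

grids_equal <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Assert that two objects share one volume grid
#'
#' @param a,b objects carrying a `grid` attribute or `volume_grid`s.
#' @param what label used in the error message.
#' @return Invisibly, the common grid.
#' @export
check_same_grid <- function(a, b, what = "volumes") {
  ga <- if (inherits(a, "volume_grid")) a else attr(a, "grid")
  gb <- if (inherits(b, "volume_grid")) b else attr(b, "grid")
  if (is.null(ga) || is.null(gb)) stop("missing grid information on ", what)
  if (!grids_equal(ga, gb)) {
    stop(sprintf("grid mismatch for %s: %s voxels vs %s voxels", what,
                 paste(ga$shape, collapse = "x"), paste(gb$shape, collapse = "x")))
  }
  invisible(ga)
}

new_volume <- function(data, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- array(as.numeric(data), dim = grid$shape)
  attr(data, "grid") <- grid
  data
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} that keep the `volume_grid` attribute in
#' step with the NIfTI header (pixdim carries the voxel size).
#'
#' @param vol 3D or 4D array with a `grid` attribute.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns an array with a `grid` attribute.
#' @export
write_volume <- function(vol, path) {
  grid <- attr(vol, "grid")
  if (is.null(grid)) stop("volume has no grid attribute")
  img <- RNifti::asNifti(unclass(vol))
  nd <- length(dim(vol))
  pd <- c(grid$voxel_size_mm, rep(1, max(0L, nd - 3L)))
  img <- RNifti::`pixdim<-`(img, pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param origin world position passed through to the grid (NIfTI sform
#'   handling is out of scope for synthetic grids).
#' @export
read_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  grid <- volume_grid(d[1:3], RNifti::pixdim(img)[1:3], origin)
  out <- array(as.numeric(img), dim = d)
  attr(out, "grid") <- grid
  out
}

# linear index <-> (i,j,k) helpers, 1-based internally
vox_index <- function(ijk, shape) {
  (ijk[, 3L] - 1L) * shape[1L] * shape[2L] + (ijk[, 2L] - 1L) * shape[1L] + ijk[, 1L]
}
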