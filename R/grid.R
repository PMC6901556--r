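#' Volume grid: the shape + affine contract shared by every volume
#'
#' A `volume_grid` records the voxel lattice (`shape`, voxels per axis) and
#' the voxel-to-world affine (4x4, millimetres) of a volume. Every
#' multi-volume operation in the package requires grid identity: the package
#' never resamples, it refuses with a grid-mismatch error instead, because
#' spatial normalization is assumed to have happened upstream.
#'
#' @param shape integer triple, voxels per axis (each >= 1).
#' @param affine 4x4 numeric voxel-to-world matrix; must be invertible and
#'   have bottom row (0,0,0,1). Voxel indices are 0-based in world mapping.
#' @return An object of class `volume_grid` with fields `shape`, `affine`
#'   and `voxel_size` (mm, the column norms of the affine's 3x3 block).
#' @examples
#' g <- volume_grid(c(91, 109, 91), diag(c(2, 2, 2, 1)))
#' g$voxel_size
#' @export
volume_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    lnm_abort("'shape' must be three integers >= 1", "lnm_grid_error")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    lnm_abort("'affine' must be a finite 4x4 matrix", "lnm_grid_error")
  if (abs(det(affine)) < 1e-12)
    lnm_abort("'affine' must be invertible", "lnm_grid_error")
  storage.mode(affine) <- "double"
  structure(
    list(shape = shape, affine = affine,
         voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "volume_grid"
  )
}

#' Test whether two volume grids are compatible
#'
#' Grids are compatible iff their shapes are identical and their affines
#' agree elementwise within an absolute tolerance of `tol` (default 1e-4 mm).
#' This is the gate in front of all map algebra; callers raise a
#' grid-mismatch error when it returns `FALSE`.
#'
#' @param a,b `volume_grid` objects.
#' @param tol absolute elementwise tolerance on the affines.
#' @return `TRUE` or `FALSE`.
#' @export
check_grid_compatible <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

# Raise unless grids match; 'what' names the offending input in the message.
assert_same_grid <- function(a, b, what = "volumes") {
  if (!check_grid_compatible(a, b))
    lnm_abort(sprintf("grid mismatch between %s (no resampling is performed)", what),
              "lnm_grid_mismatch_error")
  invisible(TRUE)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, voxel size %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}
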