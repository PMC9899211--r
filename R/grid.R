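#' Arterial territory codes
#'
#' The four major arterial territories handled by the package, in the fixed
#' storage order used for 4D probability files: anterior cerebral (ACA),
#' middle cerebral (MCA), posterior cerebral (PCA) and vertebro-basilar (VB).
#'
#' @format Character vector of length 4.
#' @export
TERRITORIES <- c("ACA", "MCA", "PCA", "VB")

#' Integer codes used in claim maps and level-2 label volumes
#'
#' Territories are coded 1 (ACA), 2 (MCA), 3 (PCA), 4 (VB); voxels claimed by
#' more than one territory carry the OVERLAP code (5) and brain voxels claimed
#' by none the UNDEFINED code (6). Background is 0.
#'
#' @format Named integer vector.
#' @export
TERRITORY_CODES <- c(ACA = 1L, MCA = 2L, PCA = 3L, VB = 4L,
                     OVERLAP = 5L, UNDEFINED = 6L)

#' Default tie-breaking priority between territories
#'
#' Deterministic order used whenever two territories tie exactly (equal
#' probability, equal distance): MCA, then PCA, then VB, then ACA — the
#' descending order of stroke frequency in typical clinical cohorts.
#'
#' @format Character vector of length 4.
#' @export
TERRITORY_PRIORITY <- c("MCA", "PCA", "VB", "ACA")

#' Describe a template voxel grid
#'
#' A grid records the array shape, the voxel size in millimetres and the
#' voxel-to-world affine of a template space. All volumes in one analysis
#' must share a grid; functions that combine volumes check this.
#'
#' @param shape Integer vector of length 3, strictly positive.
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0, 0, 0).
#' @return An object of class `"volume_grid"`.
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three strictly positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) ||
        abs(det(affine)) < .Machine$double.eps)
      stop("'affine' must be an invertible 4x4 matrix")
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(format(x$voxel_size), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(format(x$voxel_size), collapse = "x"), " mm")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (%s vs %s)",
                 what, format(a), format(b)))
  invisible(TRUE)
}

grid_of <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) {
    if (is.array(x) && length(dim(x)) == 3L)
      return(volume_grid(dim(x)))
    stop("object carries no grid and is not a 3D array")
  }
  g
}

check_shape <- function(data, grid) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(dim(data) == grid$shape))
    stop(sprintf("data shape (%s) does not match grid (%s)",
                 paste(dim(data), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

#' Validate a binary mask
#'
#' @param data 3D array expected to contain only 0 and 1.
#' @param what Name used in the error message.
#' @return The array as integer 0/1, invisibly unchanged in shape.
#' @export
as_binary <- function(data, what = "mask") {
  v <- unique(as.vector(data))
  bad <- setdiff(v, c(0, 1))
  if (length(bad))
    stop(sprintf("%s is not binary: contains value(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")))
  a <- array(as.integer(data), dim = dim(data))
  attributes(a) <- attributes(data)
  storage.mode(a) <- "integer"
  a
}
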