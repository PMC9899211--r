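#' Euclidean distance transform of a binary site set
#'
#' For every voxel, the exact Euclidean distance (in mm, honouring the voxel
#' size) to the nearest voxel of the site set. Voxels inside the set get 0;
#' if the set is empty every distance is `Inf`.
#'
#' @param sites 3D logical/binary array marking the site voxels.
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @return 3D numeric array of distances.
#' @export
distance_to <- function(sites, voxel_size = c(1, 1, 1)) {
  d <- dim(sites)
  if (length(d) != 3L) stop("'sites' must be a 3D array")
  out <- .edt3d_cpp(as.logical(sites), as.integer(d), as.numeric(voxel_size))
  array(out, dim = d)
}
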