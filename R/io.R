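#' Read a NIfTI volume
#'
#' Reads a 3D (or 4D) NIfTI file and returns the voxel data with its grid.
#' When `type = "binary"` the values are validated to be exactly {0, 1};
#' when `type = "label"` they must be non-negative integers.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param type One of `"auto"`, `"binary"`, `"label"`, `"scalar"`.
#' @return A numeric (or integer) array with a `"grid"` attribute holding the
#'   [volume_grid()] recovered from the header. 4D files are returned as 4D
#'   arrays with the grid describing the first three dimensions.
#' @export
read_volume <- function(path, type = c("auto", "binary", "label", "scalar")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L || length(d) > 4L)
    stop("expected a 3D or 4D image, got ", length(d), " dimensions: ", path)
  vox <- RNifti::pixdim(img)[seq_len(3)]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- volume_grid(d[1:3], vox, aff)
  data <- array(as.vector(img), dim = d)
  if (type == "binary") {
    if (length(d) != 3L) stop("binary volumes must be 3D: ", path)
    data <- as_binary(data, what = paste0("'", basename(path), "'"))
  } else if (type == "label") {
    if (any(data < 0) || max(abs(data - round(data))) > 0)
      stop("label volume must contain non-negative integers: ", path)
    data <- array(as.integer(round(data)), dim = d)
  }
  attr(data, "grid") <- grid
  data
}

#' Write a volume to NIfTI
#'
#' @param data 3D or 4D array; an attached `"grid"` attribute (or an explicit
#'   `grid`) supplies voxel size and affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid Optional [volume_grid()]; overrides the attribute.
#' @param datatype NIfTI on-disk datatype, e.g. `"int16"` or `"float"`.
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, grid = NULL, datatype = "auto") {
  if (is.null(grid)) grid <- attr(data, "grid")
  d <- dim(data)
  if (is.null(grid)) grid <- volume_grid(d[1:3])
  x <- array(as.vector(data), dim = d)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(grid$voxel_size, rep(1, length(d) - 3L))
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 4D probability file in the fixed territory order
#'
#' Stacks the four territory probability maps along the fourth dimension in
#' the fixed order ACA, MCA, PCA, VB, mirroring the layout of published 4D
#' territory-probability records.
#'
#' @param maps A [prob_map_set()] (or named list of 3D arrays with all four
#'   territory names).
#' @param path Output NIfTI path.
#' @return The path, invisibly.
#' @export
write_prob_maps_4d <- function(maps, path) {
  if (inherits(maps, "prob_map_set")) {
    grid <- maps$grid
    lst <- maps$maps
  } else {
    lst <- maps
    grid <- grid_of(lst[[1]])
  }
  missing <- setdiff(TERRITORIES, names(lst))
  if (length(missing))
    stop("missing territory map(s): ", paste(missing, collapse = ", "),
         " - all four of ", paste(TERRITORIES, collapse = ", "),
         " are required")
  for (s in TERRITORIES) check_shape(lst[[s]], grid)
  x <- array(0, dim = c(grid$shape, 4L))
  for (i in seq_along(TERRITORIES)) x[, , , i] <- lst[[TERRITORIES[i]]]
  attr(x, "grid") <- grid
  write_volume(x, path, grid = grid, datatype = "float")
}

#' Read a 4D probability file written by [write_prob_maps_4d()]
#'
#' @param path NIfTI path with 4 volumes in ACA, MCA, PCA, VB order.
#' @param n_subjects Optional named per-territory sample sizes.
#' @param method Method tag to record, `"average"` or `"bmm"`.
#' @return A [prob_map_set()].
#' @export
read_prob_maps_4d <- function(path, n_subjects = NULL, method = "average") {
  x <- read_volume(path)
  d <- dim(x)
  if (length(d) != 4L || d[4] != 4L)
    stop("expected a 4D file with 4 territory volumes: ", path)
  grid <- attr(x, "grid")
  maps <- stats::setNames(
    lapply(seq_len(4), function(i) array(x[, , , i], dim = d[1:3])),
    TERRITORIES)
  prob_map_set(maps, n_subjects = n_subjects, method = method, grid = grid)
}

#' Build a label lookup scheme
#'
#' The scheme mirrors the plain-text lookup tables that accompany published
#' label atlases: one row per parcel with its integer id, acronym, free-text
#' description and the id of the level-2 (major territory) parcel it merges
#' into.
#'
#' @param id Positive integer parcel ids (unique).
#' @param acronym Short parcel names.
#' @param description Free-text descriptions.
#' @param level2_id Integer id of the major territory each parcel belongs to.
#' @return A `data.frame` of class `"label_scheme"`.
#' @export
label_scheme <- function(id, acronym, description = acronym,
                         level2_id = id) {
  id <- as.integer(id)
  if (any(id < 1L)) stop("label ids must be positive")
  if (anyDuplicated(id)) stop("label ids must be unique")
  df <- data.frame(id = id, acronym = as.character(acronym),
                   description = as.character(description),
                   level2_id = as.integer(level2_id),
                   stringsAsFactors = FALSE)
  class(df) <- c("label_scheme", "data.frame")
  df
}

#' Default level-2 scheme for the four major territories
#' @return A [label_scheme()] with ids 1-4 (ACA, MCA, PCA, VB).
#' @export
territory_scheme <- function() {
  label_scheme(id = 1:4, acronym = TERRITORIES,
               description = c("Anterior cerebral artery territory",
                               "Middle cerebral artery territory",
                               "Posterior cerebral artery territory",
                               "Vertebro-basilar territory"),
               level2_id = 1:4)
}

#' Construct a label volume
#'
#' @param data 3D array of non-negative integers (0 = background).
#' @param grid A [volume_grid()]; defaults to the array's attached grid.
#' @param scheme A [label_scheme()] covering every nonzero value in `data`.
#' @return An object of class `"label_volume"`.
#' @export
label_volume <- function(data, grid = NULL, scheme = territory_scheme()) {
  if (is.null(grid)) grid <- grid_of(data)
  check_shape(data, grid)
  vals <- unique(as.vector(data))
  vals <- vals[vals != 0]
  unknown <- setdiff(vals, scheme$id)
  if (length(unknown))
    stop("label values not present in scheme: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  d <- array(as.integer(data), dim = grid$shape)
  structure(list(data = d, grid = grid, scheme = scheme),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$data[x$data != 0], levels = x$scheme$id))
  cat("<label_volume> ", format(x$grid), "\n", sep = "")
  cat("  parcels: ", sum(tab > 0), " of ", nrow(x$scheme),
      " scheme entries present; ", sum(tab), " labelled voxels\n", sep = "")
  invisible(x)
}

#' Write / read a lookup table as plain text
#'
#' Tab-separated columns `id`, `acronym`, `description`, `level2_id`.
#'
#' @param scheme A [label_scheme()].
#' @param path Output text path.
#' @return `write_label_scheme()` returns the path invisibly;
#'   `read_label_scheme()` returns a [label_scheme()].
#' @export
write_label_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_scheme
#' @export
read_label_scheme <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  label_scheme(df$id, df$acronym, df$description, df$level2_id)
}
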