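#' Strip regions for registration quality control
#'
#' Builds the three template strip regions used to score a deformed volume:
#' the outside strip of the brain mask (OSBM: voxels outside the brain
#' within `bandwidth` of its surface), the inside strip of the brain mask
#' (ISBM: brain voxels within `bandwidth` of the surface), and the outside
#' strip of the lateral ventricles (OSLV). Distances are Euclidean and
#' mm-scaled; the bandwidth is stated in voxels and converted with the
#' first voxel dimension (grids are expected isotropic).
#'
#' @param brain_mask,ventricle_mask 3D binary masks (ventricles inside the
#'   brain), sharing one grid.
#' @param bandwidth Strip width in voxels (default 5).
#' @param voxel_size Voxel edge lengths in mm (default from the mask grid,
#'   else 1 mm isotropic).
#' @return An object of class `"qc_regions"` with binary fields `osbm`,
#'   `isbm`, `oslv` and the `bandwidth`.
#' @export
make_strips <- function(brain_mask, ventricle_mask, bandwidth = 5,
                        voxel_size = NULL) {
  if (is.null(voxel_size)) {
    g <- attr(brain_mask, "grid")
    voxel_size <- if (is.null(g)) c(1, 1, 1) else g$voxel_size
  }
  brain <- as_binary(brain_mask, "brain mask")
  vent <- as_binary(ventricle_mask, "ventricle mask")
  if (!all(dim(brain) == dim(vent)))
    stop("brain and ventricle masks are not on the same grid")
  if (sum(brain) == 0L || sum(vent) == 0L)
    stop("brain and ventricle masks must be non-empty")
  if (any(vent == 1L & brain == 0L))
    stop("ventricle mask must lie inside the brain mask")
  bw_mm <- bandwidth * voxel_size[1]
  d_to_brain <- distance_to(brain == 1L, voxel_size)
  d_to_out <- distance_to(brain == 0L, voxel_size)
  d_to_vent <- distance_to(vent == 1L, voxel_size)
  osbm <- brain == 0L & d_to_brain <= bw_mm & d_to_brain > 0
  isbm <- brain == 1L & d_to_out <= bw_mm
  oslv <- vent == 0L & d_to_vent <= bw_mm & d_to_vent > 0
  if (bandwidth == 0) osbm[] <- isbm[] <- oslv[] <- FALSE
  d <- dim(brain)
  structure(list(osbm = array(as.integer(osbm), d),
                 isbm = array(as.integer(isbm), d),
                 oslv = array(as.integer(oslv), d),
                 bandwidth = bandwidth), class = "qc_regions")
}

#' @export
print.qc_regions <- function(x, ...) {
  cat("<qc_regions> bandwidth =", x$bandwidth, "voxels;",
      "OSBM", sum(x$osbm), "| ISBM", sum(x$isbm), "| OSLV", sum(x$oslv),
      "voxels\n")
  invisible(x)
}

#' Mis-registration ratios of a deformed volume
#'
#' Scores how well a deformed (subject-to-template) volume respects the
#' template geometry: `gamma_osbm` is the fraction of OSBM voxels where the
#' deformed intensity is positive (tissue spilling outside the template
#' brain), `gamma_isbm` the fraction of ISBM voxels where it is zero
#' (background intruding into the brain), and `gamma_oslv` the fraction of
#' OSLV voxels brighter than a CSF cutoff lambda (ventricle spilling
#' outside the template ventricles). By default lambda is the mean minus
#' half a standard deviation of the deformed intensities inside the
#' template ventricle mask; an alternative rule can be supplied.
#'
#' @param deformed 3D scalar volume in template space.
#' @param regions A [make_strips()] result on the same grid.
#' @param ventricle_mask Template ventricle mask (for the lambda rule).
#' @param lambda_rule Function of the ventricle intensity vector returning
#'   the cutoff; default `mean - 0.5 * sd`.
#' @return An object of class `"qc_result"` with `gamma_osbm`,
#'   `gamma_isbm`, `gamma_oslv` (each in [0, 1], `NA` for an empty strip)
#'   and `lambda`.
#' @export
qc_ratios <- function(deformed, regions, ventricle_mask,
                      lambda_rule = function(v) mean(v) - 0.5 * stats::sd(v)) {
  vent <- as_binary(ventricle_mask, "ventricle mask")
  if (!all(dim(deformed) == dim(regions$osbm)))
    stop("deformed volume is not on the strip grid")
  frac <- function(strip, cond) {
    n <- sum(strip)
    if (n == 0L) return(NA_real_)
    sum(cond & strip == 1L) / n
  }
  lam <- lambda_rule(deformed[vent == 1L])
  structure(list(
    gamma_osbm = frac(regions$osbm, deformed > 0),
    gamma_isbm = frac(regions$isbm, deformed == 0),
    gamma_oslv = frac(regions$oslv, deformed > lam),
    lambda = lam), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> gamma_OSBM = %.4f  gamma_ISBM = %.4f  gamma_OSLV = %.4f  (lambda = %.3f)\n",
    x$gamma_osbm, x$gamma_isbm, x$gamma_oslv, x$lambda))
  invisible(x)
}

#' QC report for one or many deformed volumes
#'
#' @param deformed A volume or list of volumes.
#' @param brain_mask,ventricle_mask Template masks.
#' @param bandwidth Strip width in voxels.
#' @param ... Passed to [qc_ratios()].
#' @return data.frame with one row per volume: the three gamma ratios and
#'   lambda.
#' @export
qc_report <- function(deformed, brain_mask, ventricle_mask, bandwidth = 5,
                      ...) {
  if (!is.list(deformed)) deformed <- list(deformed)
  regions <- make_strips(brain_mask, ventricle_mask, bandwidth)
  rows <- lapply(seq_along(deformed), function(i) {
    r <- qc_ratios(deformed[[i]], regions, ventricle_mask, ...)
    data.frame(volume = if (!is.null(names(deformed)))
      names(deformed)[i] else i,
      gamma_osbm = r$gamma_osbm, gamma_isbm = r$gamma_isbm,
      gamma_oslv = r$gamma_oslv, lambda = r$lambda)
  })
  do.call(rbind, rows)
}
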