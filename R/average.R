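#' Bundle per-territory probability maps
#'
#' @param maps Named list of 3D probability arrays (names from
#'   [TERRITORIES]).
#' @param n_subjects Optional named per-territory sample sizes.
#' @param method `"average"` or `"bmm"`.
#' @param grid A [volume_grid()]; defaults to the first map's grid.
#' @return An object of class `"prob_map_set"`.
#' @export
prob_map_set <- function(maps, n_subjects = NULL,
                         method = c("average", "bmm"), grid = NULL) {
  method <- match.arg(method)
  if (is.null(grid)) grid <- grid_of(maps[[1]])
  if (is.null(names(maps)) || !all(names(maps) %in% TERRITORIES))
    stop("maps must be named with territory codes")
  for (s in names(maps)) {
    check_shape(maps[[s]], grid)
    rng <- range(maps[[s]])
    if (rng[1] < 0 || rng[2] > 1)
      stop("probability map for ", s, " has values outside [0, 1]")
    attr(maps[[s]], "grid") <- NULL
  }
  structure(list(maps = maps, n_subjects = n_subjects, method = method,
                 grid = grid), class = "prob_map_set")
}

#' @export
print.prob_map_set <- function(x, ...) {
  cat("<prob_map_set> method = ", x$method, ", ", format(x$grid), "\n",
      sep = "")
  for (s in names(x$maps))
    cat(sprintf("  %-3s max p = %.3f  support = %d voxels%s\n", s,
                max(x$maps[[s]]), sum(x$maps[[s]] > 0),
                if (!is.null(x$n_subjects))
                  sprintf("  (N = %d)", x$n_subjects[[s]]) else ""))
  invisible(x)
}

#' Average-method probability map for one territory
#'
#' The classical lesion-frequency map: the voxelwise mean of the binary
#' masks of all subjects in the territory group, i.e. the count of subjects
#' lesioned at each voxel divided by the group size N_s. All masks are
#' assumed left-lateralized (see [flip_cohort_to_left()]).
#'
#' @param cohort A [lesion_cohort()].
#' @param territory Territory code.
#' @return 3D probability array (every value an integer multiple of 1/N_s).
#' @export
average_prob_map <- function(cohort, territory) {
  idx <- which(cohort$group == territory)
  if (!length(idx))
    stop("no subjects in territory group ", territory)
  acc <- array(0, cohort$grid$shape)
  for (i in idx) acc <- acc + cohort$masks[[i]]
  out <- acc / length(idx)
  attr(out, "grid") <- cohort$grid
  out
}

#' Average-method maps for all territories in a cohort
#'
#' @param cohort A [lesion_cohort()] (left-lateralized).
#' @return A [prob_map_set()] with `method = "average"`.
#' @export
average_prob_maps <- function(cohort) {
  ns <- n_subjects(cohort)
  maps <- lapply(names(ns), function(s) average_prob_map(cohort, s))
  names(maps) <- names(ns)
  prob_map_set(maps, n_subjects = ns, method = "average",
               grid = cohort$grid)
}

#' Border-zone probability-ratio map between two territories
#'
#' On the voxels where both territory probabilities are positive (the
#' two-territory border zone), the ratio p_a / p_b. Values above 1 mean the
#' voxel is more often lesioned in strokes of territory `a` than of `b`.
#' Outside the shared support the ratio is undefined and stored as `NA`,
#' with `support_mask` marking where it exists.
#'
#' @param maps A [prob_map_set()].
#' @param a,b Territory codes (numerator, denominator).
#' @return A list of class `"ratio_map"` with fields `values` (3D array,
#'   `NA` off support), `support_mask`, `numerator`, `denominator`, `grid`.
#' @export
border_ratio <- function(maps, a, b) {
  if (!all(c(a, b) %in% names(maps$maps)))
    stop("territories ", a, " and ", b, " must both be present")
  pa <- maps$maps[[a]]; pb <- maps$maps[[b]]
  sup <- (pa > 0) & (pb > 0)
  vals <- array(NA_real_, maps$grid$shape)
  vals[sup] <- pa[sup] / pb[sup]
  structure(list(values = vals,
                 support_mask = array(as.integer(sup), maps$grid$shape),
                 numerator = a, denominator = b, grid = maps$grid),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  n <- sum(x$support_mask)
  cat("<ratio_map> ", x$numerator, "/", x$denominator, ": ", n,
      " border-zone voxels", sep = "")
  if (n) cat(sprintf(", ratio range [%.3g, %.3g]",
                     min(x$values, na.rm = TRUE),
                     max(x$values, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Voxelwise certainty index
#'
#' Normalizes the territory probabilities at each voxel by their sum over
#' all territories, giving the conditional probability that the voxel
#' belongs to each territory given that it is lesioned at all. Defined on
#' the support (voxels where the summed probability is positive); outside
#' it every CI is 0 and the support mask excludes the voxel.
#'
#' @param maps A [prob_map_set()].
#' @return A list of class `"ci_maps"`: `ci` (named list of 3D arrays
#'   summing to 1 on support), `support_mask`, `grid`.
#' @export
certainty_index <- function(maps) {
  tot <- Reduce(`+`, maps$maps)
  sup <- tot > 0
  ci <- lapply(maps$maps, function(p) {
    out <- array(0, maps$grid$shape)
    out[sup] <- p[sup] / tot[sup]
    out
  })
  structure(list(ci = ci,
                 support_mask = array(as.integer(sup), maps$grid$shape),
                 grid = maps$grid),
            class = "ci_maps")
}

#' Mean certainty index per region of interest
#'
#' For every parcel of an anatomical parcellation, the mean certainty index
#' of each territory over the parcel voxels that lie on the CI support,
#' expressed in percent. Parcels with no support voxels are reported with
#' `NA` (missing), not zero.
#'
#' @param ci A [certainty_index()] result.
#' @param parcellation A [label_volume()] (or integer 3D array) on the same
#'   grid.
#' @return A data.frame with columns `roi`, `territory`, `mean_ci_pct`,
#'   `n_voxels` (support voxels contributing).
#' @export
mean_ci_by_roi <- function(ci, parcellation) {
  if (inherits(parcellation, "label_volume")) {
    stop_if_grid_mismatch(ci$grid, parcellation$grid, "CI and parcellation")
    parc <- parcellation$data
    roi_names <- stats::setNames(parcellation$scheme$acronym,
                                 parcellation$scheme$id)
  } else {
    parc <- parcellation
    check_shape(parc, ci$grid)
    roi_names <- NULL
  }
  rois <- sort(unique(as.vector(parc[parc != 0])))
  sup <- ci$support_mask == 1L
  out <- list()
  for (r in rois) {
    in_roi <- (parc == r) & sup
    n <- sum(in_roi)
    for (s in names(ci$ci)) {
      val <- if (n == 0L) NA_real_ else 100 * mean(ci$ci[[s]][in_roi])
      out[[length(out) + 1L]] <- data.frame(
        roi = if (!is.null(roi_names)) roi_names[[as.character(r)]] else r,
        territory = s, mean_ci_pct = val, n_voxels = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
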