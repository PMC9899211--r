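#' Assemble a lesion cohort
#'
#' A cohort bundles the per-subject binary lesion masks (all on one grid)
#' with the arterial-territory group label assigned to each stroke and the
#' lesioned hemisphere. Downstream map construction assumes all masks have
#' been mirrored to the left hemisphere; see [flip_cohort_to_left()].
#'
#' @param masks List of 3D binary arrays, one per subject.
#' @param group Character/factor of territory codes (`"ACA"`, `"MCA"`,
#'   `"PCA"`, `"VB"`), one per subject.
#' @param hemisphere Character of `"left"`/`"right"`, one per subject.
#' @param grid A [volume_grid()]; defaults to the first mask's grid.
#' @param subject_id Optional subject identifiers.
#' @return An object of class `"lesion_cohort"`.
#' @export
lesion_cohort <- function(masks, group, hemisphere = rep("left", length(masks)),
                          grid = NULL, subject_id = NULL) {
  n <- length(masks)
  if (n == 0L) stop("cohort has no subjects")
  if (length(group) != n || length(hemisphere) != n)
    stop("'group' and 'hemisphere' must have one entry per mask")
  group <- as.character(group)
  bad <- setdiff(unique(group), TERRITORIES)
  if (length(bad))
    stop("unknown territory code(s): ", paste(bad, collapse = ", "))
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) == 1L) hemisphere <- rep(hemisphere, n)
  if (!all(hemisphere %in% c("left", "right")))
    stop("'hemisphere' entries must be \"left\" or \"right\"")
  if (is.null(grid)) grid <- grid_of(masks[[1]])
  masks <- lapply(seq_len(n), function(i) {
    m <- as_binary(masks[[i]], what = sprintf("mask %d", i))
    check_shape(m, grid)
    attr(m, "grid") <- NULL
    m
  })
  if (is.null(subject_id))
    subject_id <- sprintf("sub-%03d", seq_len(n))
  structure(list(masks = masks, group = group, hemisphere = hemisphere,
                 grid = grid, subject_id = as.character(subject_id)),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat("<lesion_cohort> ", length(x$masks), " subjects on ",
      format(x$grid), "\n", sep = "")
  print(table(territory = x$group, hemisphere = x$hemisphere))
  invisible(x)
}

#' Number of subjects per territory
#' @param cohort A [lesion_cohort()].
#' @return Named integer vector over the territories present.
#' @export
n_subjects <- function(cohort) {
  tab <- table(factor(cohort$group, levels = TERRITORIES))
  out <- as.integer(tab)
  names(out) <- TERRITORIES
  out[out > 0L]
}

#' Mirror a right-hemisphere mask to the left
#'
#' Mirrors a mask along the x-axis (the first array dimension, taken to be
#' the left-right axis of the template) when the lesion is in the right
#' hemisphere; left-hemisphere masks are returned unchanged. The flip maps
#' 0-based voxel index i to (dim_x - 1 - i) and preserves the lesion voxel
#' count. Applying it twice with `hemisphere = "right"` recovers the input.
#'
#' @param mask 3D binary array.
#' @param hemisphere `"left"` or `"right"`.
#' @return The (possibly mirrored) mask.
#' @export
flip_to_left <- function(mask, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  mask <- as_binary(mask)
  if (hemisphere == "left") return(mask)
  out <- mask[dim(mask)[1]:1, , , drop = FALSE]
  attributes(out) <- attributes(mask)
  out
}

#' Left-lateralize every mask in a cohort
#'
#' @param cohort A [lesion_cohort()].
#' @return The cohort with right-hemisphere masks mirrored and all
#'   `hemisphere` entries set to `"left"`.
#' @export
flip_cohort_to_left <- function(cohort) {
  for (i in seq_along(cohort$masks)) {
    if (cohort$hemisphere[i] == "right") {
      cohort$masks[[i]] <- flip_to_left(cohort$masks[[i]], "right")
      cohort$hemisphere[i] <- "left"
    }
  }
  cohort
}

#' Dice overlap between two binary masks
#'
#' Dice = 2|A intersect B| / (|A| + |B|). Two empty masks are defined to
#' agree perfectly (Dice 1).
#'
#' @param a,b 3D binary arrays on the same grid.
#' @return A number in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as_binary(a, "first mask"); b <- as_binary(b, "second mask")
  if (!all(dim(a) == dim(b)))
    stop("masks are not on the same grid: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a * b) / (na + nb)
}

#' Write a cohort as a directory of mask files plus a participants table
#'
#' One NIfTI mask per subject plus `participants.tsv` with columns
#' `subject_id`, `group`, `hemisphere`.
#'
#' @param cohort A [lesion_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_mask.nii.gz", cohort$subject_id)
  for (i in seq_along(cohort$masks))
    write_volume(cohort$masks[[i]], file.path(dir, files[i]),
                 grid = cohort$grid, datatype = "uint8")
  tab <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                    hemisphere = cohort$hemisphere, mask = files,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "participants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `participants.tsv` and the mask files it
#'   names.
#' @return A [lesion_cohort()].
#' @export
read_cohort <- function(dir) {
  tsv <- file.path(dir, "participants.tsv")
  if (!file.exists(tsv)) stop("no participants.tsv in ", dir)
  tab <- utils::read.table(tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  masks <- lapply(tab$mask, function(f)
    read_volume(file.path(dir, f), type = "binary"))
  grid <- attr(masks[[1]], "grid")
  lesion_cohort(masks, tab$group, tab$hemisphere, grid = grid,
                subject_id = tab$subject_id)
}
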