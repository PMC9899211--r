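#' Closed-form claiming threshold
#'
#' The confidence rule "claim voxel j when mu + alpha * sqrt(mu (1 - mu))
#' reaches 1" is equivalent, for rates in [0, 1], to thresholding the rate
#' at 1 / (1 + alpha^2). At the default alpha = 3 the threshold is exactly
#' 0.1.
#'
#' @param alpha Non-negative confidence parameter.
#' @return The equivalent rate threshold.
#' @export
claim_threshold <- function(alpha) {
  if (alpha < 0) stop("'alpha' must be non-negative")
  1 / (1 + alpha^2)
}

priority_codes <- function(ids) {
  # territory codes in the fixed tie-break order first, then ascending ids
  terr_order <- unname(TERRITORY_CODES[TERRITORY_PRIORITY])
  c(terr_order[terr_order %in% ids], sort(setdiff(ids, terr_order)))
}

#' Territory-claimed voxel map
#'
#' A voxel is claimed by a territory when at least one of its fitted
#' cluster rate maps satisfies mu + alpha * sqrt(mu (1 - mu)) >= 1, i.e.
#' the rate is within alpha Bernoulli standard deviations of certainty.
#' Voxels claimed by exactly one territory get that territory's code;
#' voxels claimed by several get the OVERLAP code; brain voxels claimed by
#' none the UNDEFINED code (see [TERRITORY_CODES]).
#'
#' @param fits Named list of [bmm()] fits (names are territory codes), all
#'   on one grid.
#' @param brain_mask 3D binary brain mask.
#' @param alpha Confidence parameter (default 3).
#' @return An object of class `"claim_map"` with fields `data` (integer
#'   volume), `alpha`, `grid`, `territories`.
#' @export
claim_voxels <- function(fits, brain_mask, alpha = 3) {
  if (alpha < 0) stop("'alpha' must be non-negative")
  terr <- names(fits)
  if (is.null(terr) || !all(terr %in% TERRITORIES))
    stop("'fits' must be a named list keyed by territory codes")
  grid <- fits[[1]]$grid
  if (is.null(grid)) stop("fits must carry a volume support (cohort fits)")
  for (f in fits[-1]) stop_if_grid_mismatch(grid, f$grid, "fits")
  brain_mask <- as_binary(brain_mask, "brain mask")
  check_shape(brain_mask, grid)

  n_claims <- array(0L, grid$shape)
  claimed_by <- array(0L, grid$shape)
  for (s in terr) {
    mu <- unclip_rates(fits[[s]]$mu, fits[[s]]$epsilon)
    # claimed iff some cluster rate satisfies the confidence rule
    claimed_cols <- apply(mu + alpha * sqrt(mu * (1 - mu)) >= 1, 2, any)
    cl <- array(FALSE, grid$shape)
    cl[fits[[s]]$support] <- claimed_cols
    cl <- cl & brain_mask == 1L
    n_claims <- n_claims + cl
    claimed_by[cl] <- TERRITORY_CODES[[s]]
  }
  data <- array(0L, grid$shape)
  inside <- brain_mask == 1L
  data[inside] <- TERRITORY_CODES[["UNDEFINED"]]
  one <- n_claims == 1L
  data[one] <- claimed_by[one]
  data[n_claims > 1L] <- TERRITORY_CODES[["OVERLAP"]]
  structure(list(data = data, alpha = alpha, grid = grid,
                 territories = terr), class = "claim_map")
}

#' @export
print.claim_map <- function(x, ...) {
  codes <- TERRITORY_CODES[c(x$territories, "OVERLAP", "UNDEFINED")]
  tab <- vapply(codes, function(cd) sum(x$data == cd), integer(1))
  cat("<claim_map> alpha =", x$alpha, "\n")
  print(tab)
  invisible(x)
}

#' Resolve multi-territory claims
#'
#' Every OVERLAP voxel is reassigned to the territory with the largest
#' voxelwise rate maximum (mu_max) there; exact ties go to the fixed
#' priority order [TERRITORY_PRIORITY].
#'
#' @param claim A [claim_voxels()] result.
#' @param fits The same named list of fits the claim map was built from.
#' @return The claim map with no OVERLAP codes remaining.
#' @export
resolve_overlaps <- function(claim, fits) {
  ov <- claim$data == TERRITORY_CODES[["OVERLAP"]]
  if (!any(ov)) return(claim)
  idx <- which(ov)
  best_val <- rep(-Inf, length(idx))
  best_lab <- rep(0L, length(idx))
  for (s in intersect(TERRITORY_PRIORITY, names(fits))) {
    mm <- mu_max_map(fits[[s]])[idx]
    better <- mm > best_val  # strict: earlier (higher-priority) keeps ties
    best_val[better] <- mm[better]
    best_lab[better] <- TERRITORY_CODES[[s]]
  }
  claim$data[idx] <- best_lab
  claim
}

extract_label_data <- function(labels) {
  if (inherits(labels, "claim_map")) {
    list(data = labels$data, grid = labels$grid, scheme = territory_scheme(),
         undefined = TERRITORY_CODES[["UNDEFINED"]],
         overlap = TERRITORY_CODES[["OVERLAP"]])
  } else if (inherits(labels, "label_volume")) {
    list(data = labels$data, grid = labels$grid, scheme = labels$scheme,
         undefined = NA_integer_, overlap = NA_integer_)
  } else {
    list(data = labels, grid = grid_of(labels), scheme = NULL,
         undefined = NA_integer_, overlap = NA_integer_)
  }
}

#' Water-spread labels onto unclaimed brain voxels
#'
#' Every unlabeled brain voxel (code 0 or UNDEFINED) receives the label of
#' its nearest labeled voxel by Euclidean distance (mm-scaled, honouring
#' anisotropic voxels); exact distance ties go to the fixed territory
#' priority order, then ascending label id. The result labels every brain
#' voxel.
#'
#' @param labels A [claim_voxels()] result (with overlaps already
#'   resolved), a [label_volume()], or an integer 3D array.
#' @param brain_mask 3D binary brain mask.
#' @return A [label_volume()] that partitions the brain mask.
#' @export
water_spread <- function(labels, brain_mask) {
  lx <- extract_label_data(labels)
  brain_mask <- as_binary(brain_mask, "brain mask")
  check_shape(brain_mask, lx$grid)
  data <- lx$data
  if (!is.na(lx$overlap) && any(data == lx$overlap))
    stop("claim map still contains OVERLAP voxels; run resolve_overlaps()")
  if (!is.na(lx$undefined)) data[data == lx$undefined] <- 0L
  ids <- sort(unique(data[data != 0L]))
  if (!length(ids)) stop("no labeled voxels to spread from")
  todo <- which(brain_mask == 1L & data == 0L)
  if (length(todo)) {
    best_d <- rep(Inf, length(todo))
    best_l <- rep(0L, length(todo))
    for (l in priority_codes(ids)) {
      d <- distance_to(data == l, lx$grid$voxel_size)[todo]
      better <- d < best_d  # strict: earlier label keeps exact ties
      best_d[better] <- d[better]
      best_l[better] <- l
    }
    data[todo] <- best_l
  }
  scheme <- lx$scheme
  if (is.null(scheme)) scheme <- label_scheme(ids, paste0("L", ids))
  label_volume(data, lx$grid, scheme)
}

#' Sharp atlas from average-method probability maps
#'
#' Assigns each voxel with a positive probability in exactly one territory
#' to that territory; voxels positive in several territories (the border
#' zone) go to the territory with the highest probability (priority order
#' on exact ties); brain voxels with zero probability everywhere are filled
#' by [water_spread()]. The result partitions the brain mask.
#'
#' @param maps A [prob_map_set()] from the average method.
#' @param brain_mask 3D binary brain mask.
#' @return A [label_volume()] with one major-territory label per brain
#'   voxel.
#' @export
sharp_atlas_from_prob <- function(maps, brain_mask) {
  brain_mask <- as_binary(brain_mask, "brain mask")
  check_shape(brain_mask, maps$grid)
  best_p <- array(0, maps$grid$shape)
  data <- array(0L, maps$grid$shape)
  for (s in intersect(TERRITORY_PRIORITY, names(maps$maps))) {
    p <- maps$maps[[s]]
    better <- p > best_p  # strict: priority order keeps exact ties
    best_p[better] <- p[better]
    data[better] <- TERRITORY_CODES[[s]]
  }
  data[brain_mask == 0L] <- 0L
  water_spread(label_volume(data, maps$grid, territory_scheme()),
               brain_mask)
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

#' Modal (majority-vote) smoothing of a label volume
#'
#' Applies one pass of a spherical majority filter: each labeled voxel is
#' relabeled to the most frequent nonzero label within a Euclidean
#' neighborhood of the given radius (in voxels). The current label wins
#' ties; otherwise ties go to the fixed priority order. Background voxels
#' are never relabeled and never invade the brain, so the label set can
#' only shrink, never grow.
#'
#' @param labels A [label_volume()] or integer 3D array.
#' @param radius Neighborhood radius in voxels (0 = identity).
#' @return Smoothed labels, same type as the input.
#' @export
smooth_labels <- function(labels, radius = 1) {
  if (radius < 0) stop("'radius' must be non-negative")
  lx <- extract_label_data(labels)
  data <- lx$data
  if (radius == 0) return(labels)
  ids <- sort(unique(data[data != 0L]))
  if (!length(ids)) return(labels)
  offs <- ball_offsets(radius)
  counts <- lapply(ids, function(l) array(0L, dim(data)))
  names(counts) <- as.character(ids)
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(data, offs[r, ])
    for (l in ids)
      counts[[as.character(l)]] <- counts[[as.character(l)]] + (sh == l)
  }
  maxc <- Reduce(pmax, counts)
  out <- data
  inside <- data != 0L
  keep <- array(FALSE, dim(data))
  for (l in ids)  # current label keeps the voxel whenever it ties the mode
    keep <- keep | (data == l & counts[[as.character(l)]] == maxc)
  reassign <- inside & !keep
  if (any(reassign)) {
    assigned <- array(FALSE, dim(data))
    for (l in priority_codes(ids)) {
      sel <- reassign & !assigned & (counts[[as.character(l)]] == maxc)
      out[sel] <- l
      assigned <- assigned | sel
    }
  }
  if (inherits(labels, "label_volume"))
    label_volume(out, lx$grid, lx$scheme)
  else if (inherits(labels, "claim_map")) {
    labels$data <- out; labels
  } else out
}

#' Merge a level-1 atlas into the four major territories
#'
#' Replaces each level-1 parcel id by its level-2 (major territory) id from
#' the lookup scheme. Voxel counts are conserved under the mapping.
#'
#' @param labels A [label_volume()] whose scheme defines `level2_id` for
#'   every parcel.
#' @return A [label_volume()] over the level-2 ids.
#' @export
merge_to_level2 <- function(labels) {
  if (!inherits(labels, "label_volume"))
    stop("'labels' must be a label_volume")
  sc <- labels$scheme
  if (any(is.na(sc$level2_id)))
    stop("label(s) without a level-2 mapping: ",
         paste(sc$id[is.na(sc$level2_id)], collapse = ", "))
  lut <- rep(0L, max(sc$id))
  lut[sc$id] <- sc$level2_id
  data <- labels$data
  nz <- data != 0L
  data[nz] <- lut[data[nz]]
  l2 <- sort(unique(sc$level2_id))
  acro <- vapply(l2, function(i) {
    if (i >= 1 && i <= 4) TERRITORIES[i]
    else if (i %in% sc$id) sc$acronym[match(i, sc$id)]
    else paste0("T", i)
  }, character(1))
  label_volume(data, labels$grid, label_scheme(l2, acro, level2_id = l2))
}

#' Subdivide territory labels by an anatomical parcellation
#'
#' Intersects a territory label volume with an anatomical parcellation:
#' each voxel whose (territory, anatomical parcel) pair appears in the
#' mapping receives the mapped sub-territory label; unmapped intersections
#' keep the territory label. The labeled voxel set is unchanged.
#'
#' @param labels A [label_volume()] of territory labels.
#' @param anatomical A [label_volume()] or integer 3D array on the same
#'   grid.
#' @param mapping data.frame with columns `territory_id`, `anat_id`,
#'   `sub_id` and optionally `sub_acronym`, `sub_description`.
#' @return A [label_volume()] with an extended scheme: sub-labels inherit
#'   the parent territory's level-2 id.
#' @export
subdivide_by_anatomy <- function(labels, anatomical, mapping) {
  if (!inherits(labels, "label_volume"))
    stop("'labels' must be a label_volume")
  ax <- extract_label_data(anatomical)
  stop_if_grid_mismatch(labels$grid, ax$grid, "labels and parcellation")
  req <- c("territory_id", "anat_id", "sub_id")
  if (!all(req %in% names(mapping)))
    stop("mapping needs columns ", paste(req, collapse = ", "))
  data <- labels$data
  out <- data
  for (r in seq_len(nrow(mapping))) {
    sel <- data == mapping$territory_id[r] & ax$data == mapping$anat_id[r]
    out[sel] <- as.integer(mapping$sub_id[r])
  }
  sc <- labels$scheme
  new_ids <- setdiff(unique(mapping$sub_id), sc$id)
  if (length(new_ids)) {
    rows <- match(new_ids, mapping$sub_id)
    parent <- mapping$territory_id[rows]
    l2 <- sc$level2_id[match(parent, sc$id)]
    acro <- if ("sub_acronym" %in% names(mapping))
      mapping$sub_acronym[rows] else paste0("SUB", new_ids)
    desc <- if ("sub_description" %in% names(mapping))
      mapping$sub_description[rows] else acro
    sc <- label_scheme(c(sc$id, new_ids), c(sc$acronym, acro),
                       c(sc$description, desc), c(sc$level2_id, l2))
  }
  label_volume(out, labels$grid, sc)
}
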