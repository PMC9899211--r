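#' Build a phantom brain with planted territory mixture structure
#'
#' Constructs a desk-scale phantom: an ellipsoidal brain mask partitioned
#' into contiguous angular sectors (one per territory), an interior
#' ventricle mask, and for each territory a planted Bernoulli mixture with
#' K* clusters. Cluster rate maps occupy distinct radial bands of the
#' sector (the innermost band is a compact "deep" cluster, the outermost a
#' broad "peripheral" one) with constant rates drawn in [0.45, 0.9] and
#' always bounded within [0.05, 0.95]. Everything is a pure function of the
#' arguments, so the same seed reproduces the template exactly.
#'
#' @param shape Integer triple, at least 16 per axis.
#' @param n_territories Number of territories, 2 to 4; the first
#'   `n_territories` codes of [TERRITORIES] are used.
#' @param clusters_per_territory Integer vector of planted cluster counts
#'   K*, recycled over territories.
#' @param seed Integer seed controlling rate draws and the sector rotation.
#' @param pi Optional list of planted prior vectors (one per territory,
#'   each summing to 1). Default: equal priors 1/K*.
#' @return An object of class `"territory_template"` with fields `grid`,
#'   `brain_mask`, `ventricle_mask`, `true_labels` (a [label_volume()]),
#'   `territories` and `params` (per territory: `K`, `pi`, `mu` rate maps).
#' @export
make_phantom <- function(shape = c(32, 32, 32), n_territories = 4,
                         clusters_per_territory = 2, seed = 1, pi = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("phantom geometry infeasible: each axis must be at least 16 voxels")
  if (n_territories < 2 || n_territories > 4)
    stop("'n_territories' must be between 2 and 4")
  terr <- TERRITORIES[seq_len(n_territories)]
  K <- rep_len(as.integer(clusters_per_territory), n_territories)
  if (any(K < 1L)) stop("cluster counts must be positive")
  if (!is.null(pi)) {
    if (length(pi) != n_territories)
      stop("'pi' must supply one prior vector per territory")
    for (t in seq_len(n_territories)) {
      if (length(pi[[t]]) != K[t] || abs(sum(pi[[t]]) - 1) > 1e-9)
        stop("prior vector ", t, " must have K* entries summing to 1")
    }
  }
  grid <- volume_grid(shape)

  ctr <- (shape + 1) / 2
  ax <- 0.42 * shape
  ix <- slice.index(array(0L, shape), 1)
  iy <- slice.index(array(0L, shape), 2)
  iz <- slice.index(array(0L, shape), 3)
  dx <- (ix - ctr[1]) / ax[1]
  dy <- (iy - ctr[2]) / ax[2]
  dz <- (iz - ctr[3]) / ax[3]
  r2 <- dx^2 + dy^2 + dz^2
  brain <- array(as.integer(r2 <= 1), shape)
  vent <- array(as.integer(r2 <= 0.22^2), shape)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  rot <- stats::runif(1, 0, 2 * base::pi)
  theta <- (atan2(dy, dx) - rot) %% (2 * base::pi)
  sector <- pmin(floor(theta / (2 * base::pi / n_territories)) + 1L,
                 n_territories)
  labels <- array(0L, shape)
  labels[brain == 1L] <- as.integer(sector[brain == 1L])

  r <- sqrt(r2)  # normalized ellipsoidal radius in [0, 1] inside brain
  params <- vector("list", n_territories)
  names(params) <- terr
  for (t in seq_len(n_territories)) {
    Kt <- K[t]
    pit <- if (is.null(pi)) rep(1 / Kt, Kt) else as.numeric(pi[[t]])
    base_rate <- stats::runif(Kt, 0.45, 0.9)
    mu <- vector("list", Kt)
    for (k in seq_len(Kt)) {
      lo <- (k - 1) / Kt
      hi <- k / Kt
      foot <- labels == t & r >= lo & r < hi + (k == Kt) * 1e-9
      m <- array(0, shape)
      m[foot] <- pmin(pmax(base_rate[k], 0.05), 0.95)
      mu[[k]] <- m
    }
    params[[t]] <- list(K = Kt, pi = pit, mu = mu)
  }

  structure(list(grid = grid, brain_mask = brain, ventricle_mask = vent,
                 true_labels = label_volume(labels, grid,
                                            territory_scheme()[
                                              seq_len(n_territories), ]),
                 territories = terr, params = params, seed = seed),
            class = "territory_template")
}

#' @export
print.territory_template <- function(x, ...) {
  cat("<territory_template> ", format(x$grid), ", ",
      length(x$territories), " territories (",
      paste(x$territories, collapse = ", "), ")\n", sep = "")
  for (t in x$territories)
    cat("  ", t, ": K* = ", x$params[[t]]$K, ", pi* = (",
        paste(format(x$params[[t]]$pi, digits = 3), collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

#' Sample a lesion cohort from a phantom template
#'
#' For each subject in territory s, a cluster is drawn from the planted
#' priors and each voxel is then an independent Bernoulli draw from that
#' cluster's rate map. With probability `right_fraction` the mask is
#' mirrored to the right hemisphere and flagged accordingly, exercising the
#' left-lateralization step downstream.
#'
#' @param template A [make_phantom()] template.
#' @param n_per_territory Integer subject counts, recycled over the
#'   template's territories.
#' @param right_fraction Probability that a subject's lesion is mirrored to
#'   the right hemisphere. Default 0.475, the right-hemisphere rate typical
#'   of large unselected stroke cohorts.
#' @param seed Integer seed.
#' @return A [lesion_cohort()]; the planted cluster index of every subject
#'   is attached as attribute `"true_cluster"`.
#' @export
sample_cohort <- function(template, n_per_territory, right_fraction = 0.475,
                          seed = 1) {
  terr <- template$territories
  n_per <- rep_len(as.integer(n_per_territory), length(terr))
  if (any(n_per < 1L)) stop("subject counts must be at least 1")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  masks <- list(); group <- character(); hemi <- character()
  true_k <- integer()
  shape <- template$grid$shape
  for (t in seq_along(terr)) {
    p <- template$params[[terr[t]]]
    for (i in seq_len(n_per[t])) {
      k <- sample.int(p$K, 1, prob = p$pi)
      m <- array(as.integer(stats::runif(prod(shape)) < p$mu[[k]]), shape)
      h <- if (stats::runif(1) < right_fraction) "right" else "left"
      if (h == "right") m <- flip_to_left(m, "right")  # mirror is involutive
      masks[[length(masks) + 1L]] <- m
      group <- c(group, terr[t])
      hemi <- c(hemi, h)
      true_k <- c(true_k, k)
    }
  }
  cohort <- lesion_cohort(masks, group, hemi, grid = template$grid)
  attr(cohort, "true_cluster") <- true_k
  cohort
}

shift_array <- function(a, shift) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Synthesize a mis-registered B0-like volume for QC testing
#'
#' Builds a piecewise-intensity volume on the template grid (background 0,
#' brain tissue 100, ventricles 200), translates it by an integer voxel
#' shift to emulate residual misregistration, and optionally adds Gaussian
#' noise. With zero shift and zero noise the support equals the brain mask
#' exactly, so strip-metric outcomes can be enumerated by hand.
#'
#' @param template A [make_phantom()] template.
#' @param misalignment Integer voxel shift triple, each within [-5, 5].
#' @param noise_sd Standard deviation of added Gaussian noise (0 = none).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param tissue_level,ventricle_level Intensities for brain tissue and
#'   ventricle voxels.
#' @return 3D numeric array with the template grid attached.
#' @export
make_phantom_b0 <- function(template, misalignment = c(0, 0, 0),
                            noise_sd = 0, seed = 1,
                            tissue_level = 100, ventricle_level = 200) {
  shift <- as.integer(round(misalignment))
  if (length(shift) != 3L || any(abs(shift) > 5L))
    stop("'misalignment' must be three integer shifts within [-5, 5] voxels")
  b0 <- array(0, template$grid$shape)
  b0[template$brain_mask == 1L] <- tissue_level
  b0[template$ventricle_mask == 1L] <- ventricle_level
  b0 <- shift_array(b0, shift)
  if (noise_sd > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    b0 <- b0 + array(stats::rnorm(length(b0), sd = noise_sd), dim(b0))
  }
  attr(b0, "grid") <- template$grid
  b0
}
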