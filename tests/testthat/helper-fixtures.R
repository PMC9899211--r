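# Small fixtures and independent brute-force oracles used across tests.

# coordinates of every voxel of a 3D array, in R's linear storage order
all_coords <- function(d) {
  as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                        z = seq_len(d[3])))
}

# exhaustive nearest-site distance: direct minimum over all site voxels
brute_distance_to <- function(sites, voxel_size = c(1, 1, 1)) {
  d <- dim(sites)
  out <- array(Inf, d)
  site_co <- which(sites == 1, arr.ind = TRUE)
  if (nrow(site_co) == 0) return(out)
  qs <- all_coords(d)
  site_mm <- sweep(site_co, 2, voxel_size, `*`)
  q_mm <- sweep(qs, 2, voxel_size, `*`)
  chunk <- 2000L
  for (start in seq(1L, nrow(q_mm), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(q_mm))
    d2 <- outer(rowSums(q_mm[idx, , drop = FALSE]^2),
                rowSums(site_mm^2), `+`) -
      2 * q_mm[idx, , drop = FALSE] %*% t(site_mm)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# exhaustive nearest-label assignment with priority tie-break
brute_nearest_label <- function(labels, brain, voxel_size = c(1, 1, 1),
                                priority = NULL) {
  ids <- sort(unique(labels[labels != 0]))
  if (is.null(priority))
    priority <- c(unname(vascter::TERRITORY_CODES[
      vascter::TERRITORY_PRIORITY]), sort(ids))
  order_ids <- unique(priority[priority %in% ids])
  out <- labels
  todo <- which(brain == 1 & labels == 0)
  if (!length(todo)) return(out)
  dists <- lapply(order_ids, function(l)
    brute_distance_to(labels == l, voxel_size)[todo])
  for (i in seq_along(todo)) {
    dv <- vapply(dists, function(x) x[i], numeric(1))
    out[todo[i]] <- order_ids[which.min(dv)]  # which.min keeps first tie
  }
  out
}

# a deterministic small two-territory cohort with hand-placed masks
toy_cohort <- function() {
  d <- c(8, 8, 8)
  mk <- function(ix) {
    m <- array(0L, d); m[ix] <- 1L; m
  }
  masks <- list(mk(1:6), mk(4:9), mk(100:120), mk(110:130))
  lesion_cohort(masks, c("MCA", "MCA", "PCA", "PCA"))
}

# minimal bmm-classed object for arithmetic-only operations
fake_fit <- function(pi, n, mu = NULL, epsilon = 1e-6) {
  K <- length(pi)
  if (is.null(mu)) mu <- matrix(0.5, K, 2)
  structure(list(K = K, pi = pi, n = n, mu = mu, epsilon = epsilon,
                 grid = NULL, support = NULL, territory = NA_character_),
            class = "bmm")
}
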