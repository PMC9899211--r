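## Bernoulli mixture model over binary lesion masks, fitted by EM.
##
## Subjects are rows of an N x J binary matrix (J = voxels on the analysis
## support, the union of all lesioned voxels in the group). Each subject is
## generated by one of K latent clusters with prior pi_k; given the cluster,
## voxels are independent Bernoulli draws with rates mu_{k,j}. Rates are
## kept in [eps, 1 - eps] so the log-likelihood stays finite at the binary
## MLE boundary.

clip_rates <- function(mu, epsilon) pmin(pmax(mu, epsilon), 1 - epsilon)

#' Undo rate clipping at the boundary
#'
#' Maps rates at or below the clipping floor back to 0 and at or above the
#' ceiling back to 1, recovering the exact maximum-likelihood rates (e.g.
#' the average-method map for a single-cluster fit).
#'
#' @param mu Numeric vector/matrix/array of rates.
#' @param epsilon Clipping bound used during fitting.
#' @return `mu` with boundary values snapped to exact 0 / 1.
#' @export
unclip_rates <- function(mu, epsilon = 1e-6) {
  mu[mu <= epsilon] <- 0
  mu[mu >= 1 - epsilon] <- 1
  mu
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# per-subject per-cluster log Bernoulli-product likelihood, N x K
log_component_lik <- function(x, mu_c) {
  # x: N x J binary, mu_c: K x J clipped rates
  logit <- log(mu_c) - log1p(-mu_c)          # K x J
  const <- rowSums(log1p(-mu_c))             # K
  sweep(x %*% t(logit), 2, const, `+`)
}

#' Mixture log-likelihood of a set of binary masks
#'
#' Computes the observed-data log-likelihood of the Bernoulli mixture,
#' summing over subjects the log of the prior-weighted product-Bernoulli
#' component likelihoods. Evaluated in log space with a log-sum-exp over
#' clusters, so it remains finite for any clipped rates.
#'
#' @param x N x J binary matrix (subjects by voxels).
#' @param pi Prior vector of length K (sums to 1).
#' @param mu K x J rate matrix (a vector is taken as K = 1).
#' @param epsilon Rate clipping bound.
#' @return Scalar log-likelihood.
#' @export
bmm_loglik <- function(x, pi, mu, epsilon = 1e-6) {
  x <- as.matrix(x)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (length(pi) != nrow(mu))
    stop("length(pi) must equal the number of rate rows")
  mu_c <- clip_rates(mu, epsilon)
  lp <- sweep(log_component_lik(x, mu_c), 2, log(pi), `+`)
  ll <- sum(logsumexp_rows(lp))
  if (!is.finite(ll))
    stop("non-finite log-likelihood: rates must be clipped away from {0,1}")
  ll
}

#' E-step: posterior cluster responsibilities
#'
#' The probability that each subject was generated by each cluster, given
#' the current priors and rates. Rows are normalized in log space, so the
#' result is well defined even when every component likelihood underflows.
#'
#' @inheritParams bmm_loglik
#' @return N x K matrix with rows summing to 1.
#' @export
e_step <- function(x, pi, mu, epsilon = 1e-6) {
  x <- as.matrix(x)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  mu_c <- clip_rates(mu, epsilon)
  lp <- sweep(log_component_lik(x, mu_c), 2, log(pi), `+`)
  exp(lp - logsumexp_rows(lp))
}

#' M-step: update priors and rates from responsibilities
#'
#' Soft cluster sizes are N_k = sum_i r_{i,k}; priors pi_k = N_k / N; rates
#' mu_k are the responsibility-weighted means of the masks normalized by
#' N_k, then clipped to [epsilon, 1 - epsilon].
#'
#' @param x N x J binary matrix.
#' @param resp N x K responsibility matrix (rows sum to 1).
#' @param epsilon Rate clipping bound.
#' @return List with `pi` (length K) and `mu` (K x J, clipped).
#' @export
m_step <- function(x, resp, epsilon = 1e-6) {
  x <- as.matrix(x)
  resp <- as.matrix(resp)
  nk <- colSums(resp)
  if (any(nk < 1e-12)) {
    cond <- structure(
      class = c("bmm_empty_cluster", "error", "condition"),
      list(message = "a cluster emptied during the M-step", call = NULL))
    stop(cond)
  }
  mu <- (t(resp) %*% x) / nk
  list(pi = nk / nrow(x), mu = clip_rates(mu, epsilon))
}

# stack a territory's masks into an N x J matrix over the analysis support
stack_masks <- function(cohort, territory) {
  idx <- which(cohort$group == territory)
  if (!length(idx)) stop("no subjects in territory group ", territory)
  n <- length(idx)
  union_mask <- array(0L, cohort$grid$shape)
  for (i in idx) union_mask <- union_mask | cohort$masks[[i]]
  support <- array(as.logical(union_mask), cohort$grid$shape)
  j <- which(support)
  x <- matrix(0L, n, length(j))
  for (r in seq_len(n)) x[r, ] <- cohort$masks[[idx[r]]][j]
  list(x = x, support = support, grid = cohort$grid, subjects = idx)
}

#' Fit a Bernoulli mixture model to binary lesion masks
#'
#' Fits a K-cluster mixture of product-Bernoulli distributions by
#' expectation-maximization with random restarts, keeping the restart with
#' the best final log-likelihood. Each restart initializes the subject
#' responsibilities from a symmetric Dirichlet draw. Iterations alternate
#' the M-step (priors and clipped rates) and E-step until the absolute
#' log-likelihood improvement falls below `tol` or `max_iter` is reached.
#' The log-likelihood trace is non-decreasing within a run.
#'
#' With `K = 1` the fitted rate map equals the average-method lesion
#' frequency map exactly (after undoing the boundary clipping with
#' [unclip_rates()]).
#'
#' @param x An N x J binary matrix (subjects by voxels) or a
#'   [lesion_cohort()] (then `territory` selects the group and the fit
#'   carries the volume support for map reconstruction).
#' @param K Number of clusters (N >= K required).
#' @param territory Territory code when `x` is a cohort.
#' @param n_restarts Number of random restarts (default 10).
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed; the fit is a pure function of data + seed.
#' @param epsilon Rate clipping bound.
#' @param ... Passed between methods.
#' @return An object of class `"bmm"`: fields `pi`, `mu` (K x J clipped
#'   rates), `responsibilities`, `loglik`, `loglik_trace`, `K`, `n`,
#'   `converged`, `flags`, plus `support`/`grid`/`territory` for cohort
#'   fits. Standard methods: `print`, `summary`, `coef`, `logLik`,
#'   `fitted`, `predict`, `residuals`, `simulate`, `plot`.
#' @seealso [select_k()], [mu_max_map()], [cluster_expectations()],
#'   [model_moments()]
#' @export
bmm <- function(x, K = 1, ...) UseMethod("bmm")

#' @rdname bmm
#' @export
bmm.lesion_cohort <- function(x, K = 1, territory = NULL, ...) {
  if (is.null(territory)) {
    terr <- unique(x$group)
    if (length(terr) != 1L)
      stop("cohort has several territory groups; supply 'territory'")
    territory <- terr
  }
  st <- stack_masks(x, territory)
  fit <- bmm(st$x, K = K, ...)
  fit$support <- st$support
  fit$grid <- st$grid
  fit$territory <- territory
  fit
}

#' @rdname bmm
#' @export
bmm.default <- function(x, K = 1, n_restarts = 10, tol = 1e-6,
                        max_iter = 500, seed = 1, epsilon = 1e-6, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (any(x != 0L & x != 1L)) stop("mask matrix must be binary")
  n <- nrow(x); j <- ncol(x)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (n < K) stop("need at least K subjects (N = ", n, ", K = ", K, ")")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  best <- NULL
  flags <- character()
  for (r in seq_len(n_restarts)) {
    run <- NULL
    for (try in 1:5) {
      resp0 <- matrix(stats::rgamma(n * K, shape = 1), n, K)
      resp0 <- resp0 / rowSums(resp0)
      run <- tryCatch(em_run(x, resp0, tol, max_iter, epsilon),
                      bmm_empty_cluster = function(e) NULL)
      if (!is.null(run)) break
    }
    if (is.null(run)) { flags <- union(flags, "empty_cluster"); next }
    if (is.null(best) || run$loglik > best$loglik) best <- run
    if (K == 1L) break  # single-cluster fit is deterministic
  }
  if (is.null(best)) stop("all EM restarts collapsed to empty clusters")
  if (min(colSums(best$resp)) < 1) flags <- union(flags, "near_empty_cluster")
  if (K > 1L) {
    # degenerate data (e.g. identical masks) leaves clusters with identical
    # rate maps; such clusters are not distinct lesion patterns
    for (a in 1:(K - 1)) for (b in (a + 1):K)
      if (max(abs(best$mu[a, ] - best$mu[b, ])) < 1e-8)
        flags <- union(flags, "duplicate_clusters")
  }

  structure(list(K = K, pi = best$pi, mu = best$mu, data = x,
                 responsibilities = best$resp,
                 loglik = best$loglik, loglik_trace = best$trace,
                 n = n, n_voxels = j, converged = best$converged,
                 n_iter = best$n_iter, flags = flags,
                 seed = seed, n_restarts = n_restarts, tol = tol,
                 max_iter = max_iter, epsilon = epsilon,
                 support = NULL, grid = NULL, territory = NA_character_),
            class = "bmm")
}

em_run <- function(x, resp, tol, max_iter, epsilon) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    par <- m_step(x, resp, epsilon)
    ll <- bmm_loglik(x, par$pi, par$mu, epsilon)
    trace <- c(trace, ll)
    resp <- e_step(x, par$pi, par$mu, epsilon)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi = par$pi, mu = par$mu, resp = resp, loglik = ll, trace = trace,
       converged = converged, n_iter = it)
}

#' Choose the number of clusters by the minimum cluster-fraction rule
#'
#' Fits mixtures with K = 1 .. `k_max` and returns the largest K for which
#' every fitted cluster keeps at least `min_fraction` of the group's
#' subjects (soft count N_k = pi_k N). The result is always at least 1.
#'
#' @param x Binary mask matrix or [lesion_cohort()] (see [bmm()]).
#' @param k_max Largest cluster count to try.
#' @param min_fraction Minimum admissible cluster fraction (default 0.10).
#' @param ... Passed to [bmm()] (seed, restarts, territory, ...).
#' @return List of class `"bmm_selection"`: `K` (chosen), `fit` (the chosen
#'   [bmm()] fit), `fits` (all fits), `admissible` (logical per K).
#' @export
select_k <- function(x, k_max = 4, min_fraction = 0.10, ...) {
  if (k_max < 1) stop("'k_max' must be at least 1")
  fits <- vector("list", k_max)
  ok <- logical(k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- bmm(x, K = k, ...)
    nk <- fits[[k]]$pi * fits[[k]]$n
    # a K is admissible when every cluster keeps the minimum fraction and
    # represents a distinct pattern (no duplicated rate maps)
    ok[k] <- all(nk >= min_fraction * fits[[k]]$n - 1e-9) &&
      !("duplicate_clusters" %in% fits[[k]]$flags)
  }
  K <- max(which(ok))
  structure(list(K = K, fit = fits[[K]], fits = fits, admissible = ok,
                 min_fraction = min_fraction), class = "bmm_selection")
}

#' @export
print.bmm_selection <- function(x, ...) {
  cat("<bmm_selection> chose K =", x$K, "of", length(x$fits),
      "candidates (min cluster fraction", x$min_fraction, ")\n")
  for (k in seq_along(x$fits))
    cat(sprintf("  K = %d: %s  pi = (%s)\n", k,
                if (x$admissible[k]) "admissible  " else "inadmissible",
                paste(format(x$fits[[k]]$pi, digits = 2), collapse = ", ")))
  invisible(x)
}

# embed a support-length vector back into the full volume (0 elsewhere)
embed_support <- function(values, support, grid) {
  out <- array(0, grid$shape)
  out[support] <- values
  attr(out, "grid") <- grid
  out
}

#' Territory probability map from a mixture fit: the voxelwise rate maximum
#'
#' The model-based probability map P_s of a territory is the voxelwise
#' maximum of its cluster rate maps. For K = 1 this is the single rate map
#' (equal to the average-method map).
#'
#' @param fit A [bmm()] fit.
#' @param unclip Snap boundary-clipped rates back to exact 0/1 (default).
#' @return A 3D probability volume for cohort fits (zero off the analysis
#'   support), or a J-vector for matrix fits.
#' @export
mu_max_map <- function(fit, unclip = TRUE) {
  mu <- fit$mu
  if (unclip) mu <- unclip_rates(mu, fit$epsilon)
  mm <- apply(mu, 2, max)
  if (is.null(fit$support)) return(mm)
  embed_support(mm, fit$support, fit$grid)
}

#' Per-cluster expectations: soft size and expected lesion volume
#'
#' N_k = pi_k N is the expected number of subjects generated by cluster k;
#' E[V_k] = sum_j mu_{k,j} is the expected lesion volume in voxels, also
#' reported in ml given the voxel volume.
#'
#' @param fit A [bmm()] fit.
#' @param voxel_volume_ml Volume of one voxel in ml; defaults to the fit
#'   grid's voxel volume (mm^3 / 1000), or 0.001 without a grid.
#' @return data.frame with columns `cluster`, `pi`, `n_k`, `ev_voxels`,
#'   `ev_ml`.
#' @export
cluster_expectations <- function(fit, voxel_volume_ml = NULL) {
  if (is.null(voxel_volume_ml))
    voxel_volume_ml <- if (!is.null(fit$grid))
      prod(fit$grid$voxel_size) / 1000 else 0.001
  mu <- unclip_rates(fit$mu, fit$epsilon)
  ev <- rowSums(mu)
  data.frame(cluster = seq_len(fit$K), pi = fit$pi, n_k = fit$pi * fit$n,
             ev_voxels = ev, ev_ml = ev * voxel_volume_ml)
}

#' Model-implied mean map and voxel covariance
#'
#' The mixture mean is E[X] = sum_k pi_k mu_k. The covariance between
#' voxels, sum_k pi_k (diag(mu_k (1 - mu_k)) + mu_k mu_k^T) - E[X] E[X]^T,
#' is generally non-diagonal for K > 1 (the latent cluster induces
#' correlation); it is exactly diagonal for K = 1. Because the covariance
#' is quadratic in the number of voxels it is only computed on a requested
#' subset of at most 500 voxels.
#'
#' @param fit A [bmm()] fit.
#' @param voxels Optional integer indices (into the volume for cohort fits,
#'   or columns for matrix fits) at which to compute the covariance; at
#'   most 500.
#' @return List with `mean` (volume or vector) and, when `voxels` is given,
#'   `cov` (square matrix over those voxels) and `voxels`.
#' @export
model_moments <- function(fit, voxels = NULL) {
  mu <- unclip_rates(fit$mu, fit$epsilon)
  ex <- colSums(mu * fit$pi)
  mean_out <- if (is.null(fit$support)) ex else
    embed_support(ex, fit$support, fit$grid)
  out <- list(mean = mean_out)
  if (!is.null(voxels)) {
    if (length(voxels) > 500L)
      stop("covariance requested on more than 500 voxels")
    if (is.null(fit$support)) {
      cols <- voxels
      mu_v <- mu[, cols, drop = FALSE]
    } else {
      # map volume indices to support columns; off-support voxels have rate 0
      sup_idx <- which(fit$support)
      pos <- match(voxels, sup_idx)
      mu_v <- matrix(0, fit$K, length(voxels))
      hit <- !is.na(pos)
      mu_v[, hit] <- mu[, pos[hit], drop = FALSE]
    }
    ex_v <- colSums(mu_v * fit$pi)
    cv <- matrix(0, length(voxels), length(voxels))
    for (k in seq_len(fit$K)) {
      cv <- cv + fit$pi[k] *
        (diag(mu_v[k, ] * (1 - mu_v[k, ]), nrow = length(voxels)) +
           tcrossprod(mu_v[k, ]))
    }
    out$cov <- cv - tcrossprod(ex_v)
    out$voxels <- voxels
  }
  out
}

## ---- standard model-object methods ----

#' @export
print.bmm <- function(x, ...) {
  cat("Bernoulli mixture model",
      if (!is.na(x$territory)) paste0(" (", x$territory, ")"), "\n", sep = "")
  cat(sprintf("  K = %d clusters, N = %d subjects, %d voxels\n",
              x$K, x$n, x$n_voxels))
  cat(sprintf("  log-likelihood %.3f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration limit"))
  cat("  pi = (", paste(format(x$pi, digits = 3), collapse = ", "), ")\n",
      sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bmm <- function(object, ...) {
  structure(list(territory = object$territory, K = object$K,
                 n = object$n, loglik = object$loglik,
                 converged = object$converged,
                 clusters = cluster_expectations(object, ...)),
            class = "summary.bmm")
}

#' @export
print.summary.bmm <- function(x, ...) {
  cat("Bernoulli mixture model",
      if (!is.na(x$territory)) paste0(" (", x$territory, ")"),
      ": K = ", x$K, ", N = ", x$n, "\n", sep = "")
  tab <- x$clusters
  tab$n_k_rounded <- round_half_away(tab$n_k)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.bmm <- function(object, unclip = TRUE, ...) {
  list(pi = object$pi,
       mu = if (unclip) unclip_rates(object$mu, object$epsilon) else
         object$mu)
}

#' @export
logLik.bmm <- function(object, ...) {
  structure(object$loglik,
            df = (object$K - 1) + object$K * object$n_voxels,
            nobs = object$n, class = "logLik")
}

#' @export
fitted.bmm <- function(object, ...) model_moments(object)$mean

#' @export
predict.bmm <- function(object, newdata = NULL,
                        type = c("responsibility", "class"), ...) {
  type <- match.arg(type)
  resp <- if (is.null(newdata)) object$responsibilities else {
    x <- newdata_to_matrix(newdata, object)
    e_step(x, object$pi, object$mu, object$epsilon)
  }
  if (type == "responsibility") resp else max.col(resp, ties.method = "first")
}

newdata_to_matrix <- function(newdata, fit) {
  if (is.matrix(newdata)) return(newdata)
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    newdata <- list(newdata)
  if (is.list(newdata) && !is.null(fit$support)) {
    j <- which(fit$support)
    return(t(vapply(newdata, function(m) as.integer(m[j]),
                    integer(length(j)))))
  }
  stop("'newdata' must be a mask matrix, a 3D mask, or a list of 3D masks")
}

#' @export
residuals.bmm <- function(object, ...) {
  # response residuals: observed mask minus the subject's posterior-mean rate
  mu <- unclip_rates(object$mu, object$epsilon)
  object$data - object$responsibilities %*% mu
}

#' @export
simulate.bmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  mu <- unclip_rates(object$mu, object$epsilon)
  ks <- sample.int(object$K, nsim, replace = TRUE, prob = object$pi)
  out <- lapply(ks, function(k) {
    v <- as.integer(stats::runif(object$n_voxels) < mu[k, ])
    if (is.null(object$support)) v else
      embed_support(v, object$support, object$grid)
  })
  attr(out, "cluster") <- ks
  out
}

#' @export
plot.bmm <- function(x, ...) {
  graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                 xlab = "EM iteration", ylab = "log-likelihood",
                 main = sprintf("EM trace (K = %d%s)", x$K,
                                if (!is.na(x$territory))
                                  paste0(", ", x$territory) else ""), ...)
  invisible(x)
}

# round half away from zero (printed cluster sizes use this convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
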