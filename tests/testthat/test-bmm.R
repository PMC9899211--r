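test_that("mixture log-likelihood matches closed forms and a naive oracle", {
  J <- 12
  x <- matrix(rbinom(J, 1, 0.5), 1)
  expect_equal(bmm_loglik(x, 1, rep(0.5, J)), J * log(0.5))

  # MLE at the data: clip(mask) maximizes the K = 1 likelihood
  ll_mle <- bmm_loglik(x, 1, clip <- pmin(pmax(x[1, ], 1e-6), 1 - 1e-6))
  set.seed(5)
  for (r in 1:20)
    expect_lte(bmm_loglik(x, 1, runif(J, 0.01, 0.99)), ll_mle)

  # naive direct-arithmetic oracle on a tiny instance (no log-sum-exp)
  set.seed(7)
  x5 <- matrix(rbinom(30, 1, 0.5), 5, 6)
  pi <- c(0.4, 0.6)
  mu <- matrix(runif(12, 0.1, 0.9), 2, 6)
  naive <- sum(log(sapply(1:5, function(i)
    sum(sapply(1:2, function(k)
      pi[k] * prod(mu[k, ]^x5[i, ] * (1 - mu[k, ])^(1 - x5[i, ])))))))
  expect_equal(bmm_loglik(x5, pi, mu), naive, tolerance = 1e-12)
})

test_that("the E-step produces normalized, correctly ordered responsibilities", {
  set.seed(9)
  x <- matrix(rbinom(40, 1, 0.5), 4, 10)
  expect_equal(e_step(x, 1, runif(10, 0.1, 0.9)),
               matrix(1, 4, 1))

  # disjoint supports: a subject matching cluster 1 is assigned to it
  mu <- rbind(c(rep(0.9, 5), rep(0.01, 5)), c(rep(0.01, 5), rep(0.9, 5)))
  x1 <- matrix(c(rep(1L, 5), rep(0L, 5)), 1)
  r <- e_step(x1, c(0.5, 0.5), mu)
  expect_gt(r[1, 1], 0.999)
  expect_equal(rowSums(r), 1)

  # exact symmetry: mirrored clusters and a symmetric subject split 50/50
  xs <- matrix(rep(1L, 10), 1)
  mus <- rbind(c(rep(0.8, 5), rep(0.2, 5)), c(rep(0.2, 5), rep(0.8, 5)))
  expect_equal(e_step(xs, c(0.5, 0.5), mus)[1, ], c(0.5, 0.5))

  # rows normalize even when every component underflows badly
  big <- matrix(1L, 1, 3000)
  rl <- e_step(big, c(0.5, 0.5), matrix(0.01, 2, 3000))
  expect_equal(sum(rl), 1)
})

test_that("the M-step recovers weighted means and signals empty clusters", {
  x <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 0L))
  # hand-computed weighted means
  resp <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  p <- m_step(x, resp)
  nk <- colSums(resp)
  expect_equal(p$pi, nk / 3)
  expect_equal(p$mu[1, ], c(0.9 * 1 + 0.5 * 0 + 0.2 * 1,
                            0.9 * 0 + 0.5 * 1 + 0.2 * 1,
                            0.9 * 1 + 0.5 * 1 + 0.2 * 0) / nk[1])

  # uniform responsibilities with K = 1 give the average map
  p1 <- m_step(x, matrix(1, 3, 1))
  expect_equal(p1$mu[1, ], colMeans(x))

  # hard assignments give plain per-cluster means
  hard <- rbind(c(1, 0), c(1, 0), c(0, 1))
  ph <- m_step(x, hard)
  expect_equal(unclip_rates(ph$mu)[1, ], colMeans(x[1:2, ]))
  expect_equal(unclip_rates(ph$mu)[2, ], as.numeric(x[3, ]))

  expect_error(m_step(x, cbind(rep(1, 3), 0)), class = "bmm_empty_cluster")
})

test_that("a single-cluster fit reproduces the average-method map exactly", {
  tpl <- make_phantom(c(16, 16, 16), 2, c(2, 1), seed = 2)
  co <- sample_cohort(tpl, c(25, 10), right_fraction = 0.4, seed = 3)
  co <- flip_cohort_to_left(co)
  f <- bmm(co, territory = "ACA", K = 1, seed = 1)
  expect_lt(max(abs(mu_max_map(f) - average_prob_map(co, "ACA"))), 1e-12)

  f2 <- bmm(co, territory = "ACA", K = 1, seed = 1)
  expect_identical(f$pi, f2$pi)
  expect_identical(f$mu, f2$mu)
})

test_that("EM is monotone and reproducible across restarts and seeds", {
  tpl <- make_phantom(c(16, 16, 16), 2, c(2, 1), seed = 12,
                      pi = list(c(0.6, 0.4), 1))
  co <- sample_cohort(tpl, c(30, 5), right_fraction = 0, seed = 14)
  for (s in 1:5) {
    f <- bmm(co, territory = "ACA", K = 2, seed = s, n_restarts = 2)
    expect_gte(min(diff(f$loglik_trace)), -1e-8)
    expect_equal(sum(f$pi), 1, tolerance = 1e-9)
    expect_equal(rowSums(f$responsibilities), rep(1, f$n), tolerance = 1e-9)
    expect_true(all(f$mu >= f$epsilon & f$mu <= 1 - f$epsilon))
  }
  fa <- bmm(co, territory = "ACA", K = 2, seed = 42, n_restarts = 3)
  fb <- bmm(co, territory = "ACA", K = 2, seed = 42, n_restarts = 3)
  expect_identical(fa$pi, fb$pi)
})

test_that("planted mixtures are recovered and K selected by the 10% rule", {
  tpl <- make_phantom(c(32, 32, 32), 2, c(2, 1), seed = 5,
                      pi = list(c(0.7, 0.3), 1))
  co <- sample_cohort(tpl, c(120, 1), right_fraction = 0, seed = 9)
  f <- bmm(co, territory = "ACA", K = 2, seed = 2, n_restarts = 5)
  # best-permutation matching by total variation on the rate maps
  mu_hat <- unclip_rates(f$mu, f$epsilon)
  sup <- which(f$support)
  tm <- t(vapply(tpl$params$ACA$mu, function(m) m[sup],
                 numeric(length(sup))))
  perms <- list(1:2, 2:1)
  tv <- vapply(perms, function(p) sum(abs(mu_hat - tm[p, ])), numeric(1))
  p <- perms[[which.min(tv)]]
  expect_lt(max(abs(f$pi - tpl$params$ACA$pi[p])), 0.05)
  expect_lt(mean(abs(mu_hat - tm[p, ])), 0.05)

  sel <- select_k(co, territory = "ACA", k_max = 3, seed = 2, n_restarts = 4)
  expect_equal(sel$K, 2)
})

test_that("identical masks yield duplicated clusters, flagged not fatal", {
  d <- c(10, 10, 10)
  m <- array(0L, d); m[100:180] <- 1L
  co <- lesion_cohort(replicate(20, m, simplify = FALSE), rep("MCA", 20))
  f <- bmm(co, territory = "MCA", K = 2, seed = 1, n_restarts = 3)
  expect_true("duplicate_clusters" %in% f$flags)
  sel <- select_k(co, territory = "MCA", k_max = 3, seed = 1, n_restarts = 3)
  expect_equal(sel$K, 1)
})

test_that("mu_max dominates the mixture mean and reduces to mu for K = 1", {
  tpl <- make_phantom(c(16, 16, 16), 2, c(3, 1), seed = 21)
  co <- sample_cohort(tpl, c(40, 5), right_fraction = 0, seed = 22)
  f <- bmm(co, territory = "ACA", K = 3, seed = 4, n_restarts = 3)
  expect_true(all(mu_max_map(f) - fitted(f) >= -1e-12))
  avg <- average_prob_map(co, "ACA")
  expect_true(all(mu_max_map(f) - avg >= -2e-6))

  f1 <- bmm(co, territory = "ACA", K = 1, seed = 4)
  expect_equal(mu_max_map(f1, unclip = FALSE)[f1$support],
               as.numeric(f1$mu[1, ]))
})

test_that("cluster expectations reproduce printed-size arithmetic", {
  # soft sizes N_k = pi_k * N for the published VB-style priors
  f <- fake_fit(pi = c(0.721, 0.122, 0.157), n = 147)
  tab <- cluster_expectations(f, voxel_volume_ml = 0.001)
  expect_equal(tab$n_k, c(105.987, 17.934, 23.079), tolerance = 1e-9)
  expect_equal(vascter:::round_half_away(tab$n_k), c(106, 18, 23))

  f2 <- fake_fit(pi = 1, n = 4, mu = matrix(0.5, 1, 10))
  tab2 <- cluster_expectations(f2, voxel_volume_ml = 1)
  expect_equal(tab2$ev_voxels, 5)  # 10 voxels at rate 0.5
  expect_equal(tab2$ev_ml, 5)

  tpl <- make_phantom(c(16, 16, 16), 2, c(2, 1), seed = 31)
  co <- sample_cohort(tpl, c(30, 4), right_fraction = 0, seed = 32)
  ff <- bmm(co, territory = "ACA", K = 2, seed = 5, n_restarts = 3)
  expect_equal(sum(cluster_expectations(ff)$n_k), ff$n, tolerance = 1e-6)
})

test_that("model moments match the mixture algebra and Monte Carlo", {
  # K = 1: covariance is exactly diagonal
  f1 <- fake_fit(pi = 1, n = 10, mu = matrix(c(0.3, 0.6, 0.9), 1))
  mm <- model_moments(f1, voxels = 1:3)
  off <- mm$cov; diag(off) <- 0
  expect_equal(off, matrix(0, 3, 3))
  expect_equal(diag(mm$cov), c(0.3 * 0.7, 0.6 * 0.4, 0.9 * 0.1))

  # two perfectly anti-correlated voxels
  f2 <- fake_fit(pi = c(0.5, 0.5), n = 10, mu = rbind(c(1, 0), c(0, 1)))
  mm2 <- model_moments(f2, voxels = 1:2)
  expect_equal(mm2$cov[1, 2], -0.25)
  expect_equal(mm2$mean, c(0.5, 0.5))

  # Monte-Carlo check of the covariance under the generative model
  set.seed(77)
  pi3 <- c(0.6, 0.4)
  mu3 <- rbind(c(0.8, 0.2, 0.5), c(0.1, 0.9, 0.5))
  f3 <- fake_fit(pi = pi3, n = 10, mu = mu3)
  n <- 20000
  ks <- sample(1:2, n, replace = TRUE, prob = pi3)
  xs <- matrix(runif(3 * n), n, 3) < mu3[ks, ]
  emp <- cov(xs) * (n - 1) / n
  se <- 3 / sqrt(n)
  expect_lt(max(abs(emp - model_moments(f3, voxels = 1:3)$cov)), se)

  expect_error(model_moments(f3, voxels = 1:501), "500")
})

test_that("the fitted model object supports the standard methods", {
  tpl <- make_phantom(c(16, 16, 16), 2, c(2, 1), seed = 41,
                      pi = list(c(0.5, 0.5), 1))
  co <- sample_cohort(tpl, c(40, 4), right_fraction = 0, seed = 42)
  f <- bmm(co, territory = "ACA", K = 2, seed = 6, n_restarts = 3)

  expect_output(print(f), "Bernoulli mixture")
  expect_output(print(summary(f)), "cluster")
  cf <- coef(f)
  expect_equal(length(cf$pi), 2)
  expect_equal(dim(cf$mu), dim(f$mu))
  expect_equal(as.numeric(logLik(f)), f$loglik)

  # prediction on the training set agrees with stored responsibilities
  expect_equal(predict(f), f$responsibilities)
  cls <- predict(f, newdata = co$masks[which(co$group == "ACA")[1:5]],
                 type = "class")
  expect_true(all(cls %in% 1:2))

  r <- residuals(f)
  expect_equal(dim(r), c(f$n, f$n_voxels))
  expect_lt(max(abs(colMeans(r))), 0.2)  # centred around the model mean

  sims <- simulate(f, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_equal(dim(sims[[1]]), tpl$grid$shape)
  expect_true(all(unlist(sims) %in% 0:1))

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
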