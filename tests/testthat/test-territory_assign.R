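# helper: single-territory K = 1 fits with prescribed rate maps
fit_from_rates <- function(rates, grid) {
  sup <- rates > 0
  structure(list(K = 1L, pi = 1, mu = matrix(rates[sup], 1),
                 epsilon = 1e-6, support = sup, grid = grid,
                 n = 1L, n_voxels = sum(sup), territory = NA_character_),
            class = "bmm")
}

test_that("the claiming rule equals rate thresholding at 1 / (1 + alpha^2)", {
  expect_identical(claim_threshold(3), 0.1)
  expect_identical(claim_threshold(0), 1)
  for (alpha in c(0.5, 1, 2, 3)) {
    mu <- seq(0, 1, by = 1e-4)
    rule <- mu + alpha * sqrt(mu * (1 - mu)) >= 1
    thr <- mu >= claim_threshold(alpha) - 1e-12
    expect_equal(rule, thr)
  }
  # boundary arithmetic at alpha = 3
  expect_true(0.1 + 3 * sqrt(0.1 * 0.9) >= 1)
  expect_lt(0.09 + 3 * sqrt(0.09 * 0.91), 1)
})

test_that("claim maps code single claims, overlaps and undefined voxels", {
  d <- c(10, 10, 10); grid <- volume_grid(d)
  brain <- array(1L, d)
  r_mca <- array(0, d); r_pca <- array(0, d)
  r_mca[1:40] <- 0.5          # claimed by MCA
  r_pca[30:60] <- 0.2         # claimed by PCA; 30:40 overlap
  r_mca[70:80] <- 0.05        # below the alpha = 3 threshold
  fits <- list(MCA = fit_from_rates(r_mca, grid),
               PCA = fit_from_rates(r_pca, grid))
  cl <- claim_voxels(fits, brain, alpha = 3)
  expect_equal(unique(cl$data[1:29]), TERRITORY_CODES[["MCA"]])
  expect_equal(unique(cl$data[30:40]), TERRITORY_CODES[["OVERLAP"]])
  expect_equal(unique(cl$data[41:60]), TERRITORY_CODES[["PCA"]])
  expect_equal(unique(cl$data[70:80]), TERRITORY_CODES[["UNDEFINED"]])

  # claimed set equals mu_max thresholding on the whole fixture
  thr <- claim_threshold(3)
  claimed <- cl$data %in% TERRITORY_CODES[c("MCA", "PCA", "OVERLAP")]
  expect_equal(claimed, pmax(r_mca, r_pca) >= thr, ignore_attr = TRUE)

  # the claimed set is non-shrinking in alpha
  prev <- claimed
  for (alpha in c(4, 5)) {
    cla <- claim_voxels(fits, brain, alpha = alpha)
    now <- cla$data %in% TERRITORY_CODES[c("MCA", "PCA", "OVERLAP")]
    expect_true(all(now[prev]))
    prev <- now
  }
})

test_that("overlap resolution picks the largest rate with a fixed tie rule", {
  d <- c(6, 6, 6); grid <- volume_grid(d)
  brain <- array(1L, d)
  r1 <- array(0, d); r2 <- array(0, d)
  r1[1:10] <- 0.9; r2[1:10] <- 0.4     # MCA wins
  r1[11:20] <- 0.3; r2[11:20] <- 0.8   # PCA wins
  r1[21:30] <- 0.5; r2[21:30] <- 0.5   # exact tie -> MCA (priority)
  fits <- list(PCA = fit_from_rates(r2, grid),
               MCA = fit_from_rates(r1, grid))
  cl <- claim_voxels(fits, brain, alpha = 3)
  expect_true(all(cl$data[1:30] == TERRITORY_CODES[["OVERLAP"]]))
  res <- resolve_overlaps(cl, fits)
  expect_true(all(res$data[1:10] == TERRITORY_CODES[["MCA"]]))
  expect_true(all(res$data[11:20] == TERRITORY_CODES[["PCA"]]))
  expect_true(all(res$data[21:30] == TERRITORY_CODES[["MCA"]]))
  expect_false(any(res$data == TERRITORY_CODES[["OVERLAP"]]))

  res2 <- resolve_overlaps(res, fits)  # idempotent when nothing overlaps
  expect_identical(res2$data, res$data)
})

test_that("water-spreading labels every brain voxel by nearest territory", {
  d <- c(5, 5, 5)
  brain <- array(1L, d)
  lab <- array(0L, d)
  lab[1, , ] <- TERRITORY_CODES[["MCA"]]
  lab[5, , ] <- TERRITORY_CODES[["PCA"]]
  lv <- water_spread(lab, brain)
  # voxel at x = 3 is equidistant: priority gives MCA
  expect_equal(unique(as.vector(lv$data[3, , ])), TERRITORY_CODES[["MCA"]])
  expect_equal(unique(as.vector(lv$data[2, , ])), TERRITORY_CODES[["MCA"]])
  expect_equal(unique(as.vector(lv$data[4, , ])), TERRITORY_CODES[["PCA"]])
  expect_true(all(lv$data[brain == 1L] != 0))

  full <- lab; full[full == 0L] <- TERRITORY_CODES[["MCA"]]
  expect_identical(water_spread(full, brain)$data, full)

  expect_error(water_spread(array(0L, d), brain), "no labeled voxels")

  # brute-force nearest-label oracle on random small fixtures
  set.seed(17)
  for (trial in 1:3) {
    dd <- c(9, 8, 7)
    br <- array(as.integer(runif(prod(dd)) < 0.9), dd)
    la <- array(0L, dd)
    seeds <- sample(which(br == 1L), 25)
    la[seeds] <- sample(1:4, 25, replace = TRUE)
    got <- water_spread(la, br)$data
    want <- brute_nearest_label(la, br)
    expect_identical(got[br == 1L], as.integer(want[br == 1L]))
  }
})

test_that("the sharp atlas is the probability argmax with nearest fill", {
  tpl <- make_phantom(c(16, 16, 16), 3, 1, seed = 51)
  co <- sample_cohort(tpl, 12, right_fraction = 0, seed = 52)
  avg <- average_prob_maps(co)
  atlas <- sharp_atlas_from_prob(avg, tpl$brain_mask)

  # oracle: per-voxel argmax (priority ties) + brute-force nearest fill
  d <- tpl$grid$shape
  want <- array(0L, d)
  bestp <- array(0, d)
  for (s in intersect(TERRITORY_PRIORITY, names(avg$maps))) {
    p <- avg$maps[[s]]
    upd <- p > bestp
    bestp[upd] <- p[upd]
    want[upd] <- TERRITORY_CODES[[s]]
  }
  want[tpl$brain_mask == 0L] <- 0L
  want <- brute_nearest_label(want, tpl$brain_mask)
  expect_identical(atlas$data, array(as.integer(want), d))
  # partitions the brain
  expect_true(all((atlas$data != 0) == (tpl$brain_mask == 1L)))
})

test_that("modal smoothing removes islands without inventing labels", {
  d <- c(9, 9, 9)
  lab <- array(TERRITORY_CODES[["MCA"]], d)
  lab[5, 5, 5] <- TERRITORY_CODES[["PCA"]]  # single-voxel island
  sm <- smooth_labels(lab, 1)
  expect_equal(sm[5, 5, 5], TERRITORY_CODES[["MCA"]])

  hom <- array(TERRITORY_CODES[["VB"]], d)
  expect_equal(smooth_labels(hom, 1), hom)
  expect_identical(smooth_labels(lab, 0), lab)

  # background never invades, label set never grows
  lab2 <- array(0L, d)
  lab2[4:6, 4:6, 4:6] <- TERRITORY_CODES[["PCA"]]
  lab2[5, 5, 5] <- TERRITORY_CODES[["ACA"]]
  sm2 <- smooth_labels(lab2, 1)
  expect_identical(sm2 != 0, lab2 != 0)
  expect_true(all(unique(sm2[sm2 != 0]) %in% unique(lab2[lab2 != 0])))
})

test_that("level-2 merge and anatomical subdivision conserve voxels", {
  d <- c(8, 8, 8); grid <- volume_grid(d)
  sc <- label_scheme(c(2, 21, 22, 3), c("MCA", "MCAf", "MCAp", "PCA"),
                     level2_id = c(2, 2, 2, 3))
  lab <- array(0L, d)
  lab[1:20] <- 21L; lab[21:30] <- 22L; lab[31:40] <- 2L; lab[41:50] <- 3L
  lv <- label_volume(lab, grid, sc)
  l2 <- merge_to_level2(lv)
  expect_equal(sum(l2$data == 2L), 40)  # MCAf + MCAp + MCA
  expect_equal(sum(l2$data == 3L), 10)
  expect_setequal(unique(l2$data[l2$data != 0]), c(2L, 3L))

  ident <- label_volume(array(c(rep(2L, 10), rep(0L, prod(d) - 10)), d),
                        grid, territory_scheme())
  expect_identical(merge_to_level2(ident)$data, ident$data)

  # subdivision by an anatomical parcellation
  terr <- label_volume(array(c(rep(2L, 30), rep(3L, 10),
                               rep(0L, prod(d) - 40)), d),
                       grid, territory_scheme())
  anat <- array(0L, d); anat[1:15] <- 7L; anat[16:30] <- 8L
  mapping <- data.frame(territory_id = c(2, 2), anat_id = c(7, 8),
                        sub_id = c(21, 22),
                        sub_acronym = c("MCAf", "MCAp"))
  sub <- subdivide_by_anatomy(terr, anat, mapping)
  expect_equal(sum(sub$data == 21L), 15)
  expect_equal(sum(sub$data == 22L), 15)
  expect_equal(sum(sub$data == 3L), 10)   # unmapped territory untouched
  expect_identical(sub$data != 0, terr$data != 0)
  # merging the subdivided atlas back recovers the major territories
  back <- merge_to_level2(sub)
  expect_identical(back$data, terr$data)

  expect_error(subdivide_by_anatomy(terr, array(0L, c(4, 4, 4)), mapping),
               "grid")
})

test_that("claim, resolve and spread partition the brain exactly once", {
  tpl <- make_phantom(c(16, 16, 16), 4, c(1, 2, 1, 2), seed = 61)
  co <- sample_cohort(tpl, 15, right_fraction = 0.3, seed = 62)
  co <- flip_cohort_to_left(co)
  fits <- lapply(stats::setNames(TERRITORIES, TERRITORIES), function(s)
    bmm(co, territory = s, K = 1, seed = 7))
  cl <- claim_voxels(fits, tpl$brain_mask, alpha = 3)
  res <- resolve_overlaps(cl, fits)
  atlas <- water_spread(res, tpl$brain_mask)
  inside <- tpl$brain_mask == 1L
  expect_true(all(atlas$data[inside] %in% TERRITORY_CODES[TERRITORIES]))
  expect_true(all(atlas$data[!inside] == 0L))
})
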