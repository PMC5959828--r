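mask_from <- function(v, dims = NULL, spacing = NULL) {
  a <- array(v, dims %||% dim(v))
  grid_image(a, spacing = spacing, pixel_kind = "label")
}

test_that("majority vote applies the strict-majority tie rule", {
  r1 <- mask_from(c(1, 0, 1, 0), c(2, 2))
  expect_equal(majority_vote(list(r1))$values, r1$values)

  r2 <- mask_from(c(1, 1, 0, 0), c(2, 2))
  r3 <- mask_from(c(1, 0, 0, 1), c(2, 2))
  mv <- majority_vote(list(r1, r2, r3))
  expect_equal(as.numeric(mv$values), c(1, 0, 0, 0))

  # two raters disagreeing -> background (a tie is not a strict majority)
  mv2 <- majority_vote(list(r1, r2))
  expect_equal(as.numeric(mv2$values), c(1, 0, 0, 0))

  # permutation invariance
  mv3 <- majority_vote(list(r3, r1, r2))
  expect_identical(mv3$values, mv$values)

  shifted <- r2; shifted$origin <- c(4, 0)
  expect_error(majority_vote(list(r1, shifted)), class = "SpatialMismatchError")
})

test_that("STAPLE reaches the perfect-agreement fixed point", {
  truth <- make_sphere_mask(c(12, 12, 12), 1, center = rep(5.5, 3), radius = 4)
  res <- staple(list(truth, truth, truth))
  expect_true(all(res$p > 0.99))
  expect_true(all(res$q > 0.99))
  expect_equal(res$consensus$values, truth$values)
  expect_true(all(res$weight_map$values >= 0 & res$weight_map$values <= 1))
  w <- res$weight_map$values
  expect_true(all(abs(w - truth$values) < 0.01))
})

test_that("STAPLE matches a hand-iterated EM on a small example", {
  # 6 voxels, 2 raters; run exactly two EM iterations in both paths
  d1 <- c(1, 1, 1, 0, 0, 0)
  d2 <- c(1, 1, 0, 0, 0, 1)
  r1 <- mask_from(d1, c(3, 2)); r2 <- mask_from(d2, c(3, 2))
  res <- staple(list(r1, r2), max_iter = 2L, tol = 0)

  D <- cbind(d1, d2)
  gamma <- mean(colMeans(D))
  p <- c(0.99, 0.99); q <- c(0.99, 0.99)
  W <- rep(gamma, 6)
  for (it in 1:2) {
    a <- gamma * apply(t(p^t(D) * (1 - p)^t(1 - D)), 1, prod)
    b <- (1 - gamma) * apply(t((1 - q)^t(D) * q^t(1 - D)), 1, prod)
    W <- a / (a + b)
    p <- colSums(W * D) / sum(W)
    q <- colSums((1 - W) * (1 - D)) / sum(1 - W)
  }
  expect_equal(as.numeric(res$weight_map$values), as.numeric(W), tolerance = 1e-12)
  expect_equal(res$p, as.numeric(p), tolerance = 1e-12)
  expect_equal(res$q, as.numeric(q), tolerance = 1e-12)
})

test_that("STAPLE recovers simulated rater performance and permutes with raters", {
  truth <- make_sphere_mask(c(24, 24, 24), 1, center = rep(11.5, 3), radius = 7)
  raters <- make_rater_stack(truth, 5L, sensitivity = 0.9, specificity = 0.95,
                             seed = 11)
  res <- staple(raters)
  expect_true(all(abs(res$p - 0.9) < 0.07))
  expect_true(all(abs(res$q - 0.95) < 0.03))

  perm <- c(3, 1, 5, 2, 4)
  res_perm <- staple(raters[perm])
  expect_equal(res_perm$p, res$p[perm], tolerance = 1e-6)
  expect_equal(res_perm$q, res$q[perm], tolerance = 1e-6)

  empty <- truth; empty$values[] <- 0
  expect_error(staple(list(empty, empty)), class = "DegenerateInputError")
  expect_error(staple(list(truth)), class = "ParameterError")
})

test_that("overlap measures follow their count definitions", {
  e <- mask_from(c(rep(1, 8), rep(0, 8)), c(4, 4))
  expect_equal(overlap_measures(e, e)$dice, 1)
  expect_equal(overlap_measures(e, e)$jaccard, 1)
  expect_equal(overlap_measures(e, e)$false_negative_fraction, 0)
  expect_equal(overlap_measures(e, e)$false_positive_fraction, 0)

  r <- mask_from(c(rep(0, 8), rep(1, 8)), c(4, 4))
  ov <- overlap_measures(e, r)
  expect_equal(ov$dice, 0); expect_equal(ov$jaccard, 0)
  expect_equal(ov$false_negative_fraction, 1)
  expect_equal(ov$false_positive_fraction, 1)

  # |E| = |R| = 100, |intersection| = 50
  ev <- mask_from(c(rep(1, 100), rep(0, 100)), c(10, 20))
  rv <- mask_from(c(rep(0, 50), rep(1, 100), rep(0, 50)), c(10, 20))
  ov2 <- overlap_measures(ev, rv)
  expect_equal(ov2$dice, 0.5)
  expect_equal(ov2$jaccard, 1 / 3)
  expect_equal(ov2$volume_similarity, 0)

  zero <- mask_from(rep(0, 16), c(4, 4))
  expect_error(overlap_measures(zero, zero), class = "UndefinedMeasureError")
})

test_that("dice equals 2*jaccard/(1 + jaccard) on random mask pairs", {
  set.seed(17)
  for (i in 1:25) {
    a <- small_mask(c(8, 8, 4), p = runif(1, 0.2, 0.6))
    b <- small_mask(c(8, 8, 4), p = runif(1, 0.2, 0.6))
    ov <- overlap_measures(a, b)
    expect_equal(ov$dice, 2 * ov$jaccard / (1 + ov$jaccard), tolerance = 1e-12)
    expect_lte(ov$jaccard, ov$dice + 1e-12)
  }
})

test_that("distance map is exact against brute force and respects spacing", {
  single <- mask_from(c(0, 0, 0, 0, 1, 0, 0, 0, 0), c(3, 3))
  dm <- distance_map(single)
  expect_equal(dm$values[2, 1], 1)
  expect_equal(dm$values[1, 1], sqrt(2))

  anis <- mask_from(rep(0, 27), c(3, 3, 3), spacing = c(2, 1, 1))
  anis$values[2, 2, 2] <- 1
  dma <- distance_map(anis)
  expect_equal(dma$values[1, 2, 2], 2)  # one voxel along axis 1 = 2 mm
  expect_equal(dma$values[2, 1, 2], 1)

  set.seed(23)
  for (i in 1:15) {
    sz <- sample(5:12, 3, replace = TRUE)
    m <- small_mask(sz, p = 0.25, spacing = runif(3, 0.5, 2))
    if (!any(m$values == 1) || all(m$values == 1)) next
    dm <- distance_map(m)
    expect_lt(max(abs(as.numeric(dm$values) -
                      oracle_surface_distance(m$values, m$spacing))), 1e-9)
  }

  signed <- distance_map(single, signed = TRUE)
  expect_equal(signed$values[2, 2], 0)
  expect_true(all(signed$values[single$values == 0] >= 0))

  full <- mask_from(rep(1, 9), c(3, 3))
  expect_error(distance_map(full), class = "DegenerateInputError")
  none <- mask_from(rep(0, 9), c(3, 3))
  expect_error(distance_map(none), class = "DegenerateInputError")
})

test_that("surface voxels are foreground with a face-adjacent background", {
  single <- mask_from(c(0, 0, 0, 0, 1, 0, 0, 0, 0), c(3, 3))
  expect_identical(surface_voxels(single)$values, single$values)

  cube <- mask_from(rep(0, 125), c(5, 5, 5))
  cube$values[2:4, 2:4, 2:4] <- 1
  sv <- surface_voxels(cube)
  expect_equal(sum(sv$values), 26)         # all but the center of a 3^3 block
  expect_equal(sv$values[3, 3, 3], 0)

  border <- mask_from(rep(1, 9), c(3, 3))  # image border counts as background
  expect_equal(sum(surface_voxels(border)$values), 8)

  empty <- mask_from(rep(0, 9), c(3, 3))
  expect_true(all(surface_voxels(empty)$values == 0))
})

test_that("surface distances are directed and match constructions", {
  slab <- function(col) {
    m <- array(0, c(8, 8)); m[col, ] <- 1
    grid_image(m, pixel_kind = "label")
  }
  a <- slab(2); b <- slab(7)
  sd_ab <- surface_distance_measures(a, b)
  expect_equal(sd_ab$mean, 5); expect_equal(sd_ab$max, 5)

  same <- surface_distance_measures(a, a)
  expect_equal(same$mean, 0); expect_equal(same$max, 0)

  # asymmetric pair: a small blob inside a large one
  big <- mask_from(rep(0, 100), c(10, 10)); big$values[2:9, 2:9] <- 1
  small <- mask_from(rep(0, 100), c(10, 10)); small$values[5:6, 5:6] <- 1
  fwd <- surface_distance_measures(small, big)
  bwd <- surface_distance_measures(big, small)
  expect_false(isTRUE(all.equal(fwd$mean, bwd$mean)))
  expect_gte(fwd$max, fwd$mean)
  expect_gte(bwd$max, bwd$mean)
})
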