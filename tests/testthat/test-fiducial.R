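test_that("Otsu threshold separates a two-level image and matches exhaustive search", {
  x <- c(rep(0, 900), rep(100, 100))
  thr <- otsu_threshold(x, n_bins = 64L)
  expect_gt(thr, 0); expect_lt(thr, 100)
  expect_equal(sum(x > thr), 100)

  set.seed(3)
  for (i in 1:30) {
    y <- c(rnorm(400, runif(1, 5, 20), runif(1, 1, 4)),
           rnorm(sample(50:400, 1), runif(1, 40, 80), runif(1, 2, 6)))
    nb <- sample(c(32L, 64L, 128L), 1)
    expect_equal(otsu_threshold(y, nb), oracle_otsu(y, nb), tolerance = 1e-12)
  }

  # shifting intensities shifts the threshold by the same amount
  y <- c(rnorm(500, 10, 2), rnorm(200, 40, 3))
  expect_equal(otsu_threshold(y + 7, 64L), otsu_threshold(y, 64L) + 7,
               tolerance = 1e-9)

  expect_error(otsu_threshold(rep(3, 100)), class = "ConstantImageError")
})

test_that("largest_component keeps the biggest blob with a lexicographic tie-break", {
  m <- array(0, c(10, 10))
  m[2:4, 2:4] <- 1          # 9 voxels
  m[8:9, 8] <- 1            # 2 voxels
  img <- grid_image(m, pixel_kind = "label")
  lc <- largest_component(img)
  expect_equal(sum(lc$values), 9)
  expect_equal(lc$values[3, 3], 1)
  expect_equal(lc$values[8, 8], 0)

  tie <- array(0, c(7, 7))
  tie[2, 2] <- 1; tie[6, 6] <- 1
  lt <- largest_component(grid_image(tie, pixel_kind = "label"))
  expect_equal(sum(lt$values), 1)
  expect_equal(lt$values[2, 2], 1)  # smaller zero-based index (1,1) wins

  # full connectivity bridges a diagonal that face connectivity separates
  diagm <- array(0, c(4, 4)); diagm[1, 1] <- 1; diagm[2, 2] <- 1; diagm[2, 3] <- 1
  expect_equal(sum(largest_component(grid_image(diagm, pixel_kind = "label"),
                                     "face")$values), 2)
  expect_equal(sum(largest_component(grid_image(diagm, pixel_kind = "label"),
                                     "full")$values), 3)

  expect_error(largest_component(grid_image(array(0, c(3, 3)), pixel_kind = "label")),
               class = "DegenerateInputError")
})

test_that("blob centroid and equivalent radius follow the volume formula", {
  m <- array(0, c(8, 8, 8)); m[4, 5, 6] <- 1
  img <- grid_image(m, origin = c(1, 2, 3), pixel_kind = "label")
  fit <- blob_centroid_radius(img)
  expect_equal(fit$center, index_to_physical(img, c(3, 4, 5)))
  expect_equal(fit$radius, (3 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0)

  sph <- make_sphere_mask(c(32, 32, 32), 1, center = c(10, 20, 14), radius = 5)
  fit2 <- blob_centroid_radius(sph)
  expect_lt(max(abs(fit2$center - c(10, 20, 14))), 0.2)
  expect_lt(abs(fit2$radius - 5), 0.2)

  # anisotropic spacing enters through the voxel volume
  ani <- grid_image(array(c(1, rep(0, 7)), c(2, 2, 2)),
                    spacing = c(2, 1, 0.5), pixel_kind = "label")
  expect_equal(blob_centroid_radius(ani)$radius,
               (3 * 1 / (4 * pi))^(1 / 3), tolerance = 1e-12)
})

test_that("edge detection finds steps and sphere shells where they are", {
  expect_error(detect_edges(grid_image(array(5, c(8, 8, 8))), 1, 0.1, 0.5),
               class = "EmptyResultError")

  step <- array(0, c(20, 12, 12)); step[11:20, , ] <- 10
  simg <- grid_image(step)
  pts <- detect_edges(simg, sigma = 1, low = 1, high = 3)
  expect_gt(nrow(pts), 0)
  expect_true(all(abs(pts[, 1] - 9.5) <= 1.0))  # step plane at x = 9.5

  vol <- make_fiducial_volume(c(32, 32, 32), 1, center = c(16, 15, 17),
                              radius = 6, noise_sigma = 0)
  ep <- detect_edges(vol, sigma = 1, low = 5, high = 15)
  rad <- sqrt(rowSums(sweep(ep, 2, c(16, 15, 17))^2))
  expect_true(all(abs(rad - 6) <= 1.5))
})

test_that("sphere fitting is exact on clean data and accurate under noise", {
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  pts6 <- sweep(base * 4, 2, c(1, 2, 3), `+`)
  fit <- fit_sphere(pts6)
  expect_lt(max(abs(fit$center - c(1, 2, 3))), 1e-9)
  expect_lt(abs(fit$radius - 4), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  set.seed(12)
  u <- matrix(rnorm(1500), ncol = 3); u <- u / sqrt(rowSums(u^2))
  clean <- sweep(u * 7.5, 2, c(-2, 4, 1), `+`)
  noisy <- clean + matrix(rnorm(1500, 0, 0.1), ncol = 3)
  fitn <- fit_sphere(noisy)
  expect_lt(max(abs(fitn$center - c(-2, 4, 1))), 0.05)
  expect_lt(abs(fitn$radius - 7.5), 0.05)

  # refinement never worsens the geometric RMS
  fit_alg <- fit_sphere(noisy, refine = FALSE)
  expect_lte(fitn$rms_residual, fit_alg$rms_residual + 1e-12)

  coplanar <- cbind(matrix(runif(40), 20, 2), 0)
  expect_error(fit_sphere(coplanar), class = "SingularFitError")
  expect_error(fit_sphere(pts6[1:3, ]), class = "SingularFitError")
})

test_that("Monte-Carlo sphere-fit scatter shrinks roughly like 1/sqrt(n)", {
  err_at_n <- function(n, reps = 12) {
    errs <- numeric(reps)
    for (r in seq_len(reps)) {
      u <- matrix(rnorm(3 * n), ncol = 3); u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * 5, 2, c(0, 0, 0), `+`) + matrix(rnorm(3 * n, 0, 0.2), ncol = 3)
      errs[r] <- sqrt(sum(fit_sphere(pts)$center^2))
    }
    mean(errs)
  }
  set.seed(77)
  e_small <- err_at_n(60)
  e_big <- err_at_n(960)
  expect_lt(e_big, e_small / 2)  # sqrt(16) = 4 expected; demand at least 2
})

test_that("fiducial localization agrees across methods and is ROI-invariant", {
  vol <- make_fiducial_volume(c(48, 48, 48), 1, center = c(24.3, 22.1, 25.6),
                              radius = 6, background = 10, contrast = 100,
                              noise_sigma = 1, seed = 5)
  roi <- box_roi(c(12, 10, 13), c(26, 26, 26))
  fit_otsu <- localize_fiducial(vol, roi, "otsu")
  fit_edge <- localize_fiducial(vol, roi, "edge")
  truth <- c(24.3, 22.1, 25.6)
  expect_lt(sqrt(sum((fit_otsu$center - truth)^2)), 0.5)
  expect_lt(sqrt(sum((fit_edge$center - truth)^2)), 0.5)
  expect_lt(sqrt(sum((fit_otsu$center - fit_edge$center)^2)), 0.5)
  expect_lt(abs(fit_otsu$radius - 6), 0.5)

  # shifting the ROI while keeping the fiducial inside changes nothing:
  # the crop stays in world coordinates
  roi2 <- box_roi(c(9, 8, 11), c(30, 29, 30))
  fit_shift <- localize_fiducial(vol, roi2, "otsu")
  expect_lt(max(abs(fit_shift$center - fit_otsu$center)), 1e-9)
  expect_equal(fit_shift$radius, fit_otsu$radius)

  # an ROI that misses the fiducial fails loudly
  vol0 <- make_fiducial_volume(c(48, 48, 48), 1, center = c(24.3, 22.1, 25.6),
                               radius = 6, noise_sigma = 0)
  empty_roi <- box_roi(c(0, 0, 0), c(8, 8, 8))
  expect_error(localize_fiducial(vol0, empty_roi, "edge"),
               class = "EmptyResultError")
  expect_error(localize_fiducial(vol0, empty_roi, "otsu"),
               class = "ConstantImageError")
})
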