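make_small_pair <- function(truth = NULL, remap = "identity", sz = 32L) {
  truth <- truth %||% translation_transform(c(2, -1.5, 1))
  make_registration_pair(truth, remap, size = rep(sz, 3L), seed = 20)
}

test_that("the virtual-domain chain maps fixed points through T_opt(T_m(T_f^-1(p)))", {
  img <- make_blob_image(c(8, 8, 8), 1, centers = matrix(c(4, 4, 4), 1),
                         sigmas = 3, amplitudes = 1)
  prob <- registration_problem(img, img, identity_transform(3))
  p <- c(1, 2, 3)
  expect_equal(map_fixed_to_moving(prob, identity_transform(3), p), p)
  expect_equal(map_fixed_to_moving(prob, translation_transform(c(1, 2, 0)), p),
               p + c(1, 2, 0))

  set.seed(3)
  for (i in 1:20) {
    tf <- random_rigid3(); tm <- random_rigid3(); topt <- random_rigid3()
    prob2 <- registration_problem(img, img, topt, t_fixed = tf, t_moving = tm)
    x <- rnorm(3)
    tf_inv <- invert_transform(tf)
    manual <- oracle_nested_apply(list(topt, tm, tf_inv), x)
    expect_equal(map_fixed_to_moving(prob2, topt, x), manual, tolerance = 1e-9)
  }
})

test_that("geometric-center initialization aligns physical extent centers", {
  a <- grid_image(array(0, c(10, 10, 10)))
  init <- initialize_geometric_center(a, a, "rigid")
  expect_equal(init$t, c(0, 0, 0))
  expect_equal(init$A, diag(3))
  expect_equal(init$center, c(4.5, 4.5, 4.5))

  b <- grid_image(array(0, c(10, 10, 10)), origin = c(5, 0, 0))
  init2 <- initialize_geometric_center(a, b, "translation")
  expect_equal(init2$t, c(5, 0, 0))
  expect_equal(apply_transform(init2, physical_center(a)), physical_center(b))

  # rotated direction: centers computed through the direction matrix
  dirm <- random_orthonormal(3)
  c_ <- grid_image(array(0, c(6, 8, 10)), origin = c(1, 2, 3),
                   spacing = c(1, 2, 1), direction = dirm)
  init3 <- initialize_geometric_center(a, c_, "rigid")
  half_idx <- (image_size(c_) - 1) / 2
  expect_equal(apply_transform(init3, physical_center(a)),
               index_to_physical(c_, half_idx), tolerance = 1e-12)
})

test_that("mean-squares metric matches closed forms", {
  img <- make_blob_image(c(16, 16, 16), 1, centers = matrix(c(8, 8, 8), 1),
                         sigmas = 4, amplitudes = 1)
  prob <- registration_problem(img, img, identity_transform(3))
  set.seed(6)
  pts <- index_to_physical(img, arrayInd(sample.int(16^3, 500), rep(16L, 3)) - 1)
  expect_equal(metric_mean_squares(prob, identity_transform(3), pts), 0)

  a <- grid_image(array(3, c(8, 8))); b <- grid_image(array(7.5, c(8, 8)))
  prob2 <- registration_problem(a, b, identity_transform(2))
  pts2 <- index_to_physical(a, arrayInd(1:64, c(8L, 8L)) - 1)
  expect_equal(metric_mean_squares(prob2, identity_transform(2), pts2),
               (3 - 7.5)^2)

  # ramp image under a known shift: squared slope * shift^2
  ramp <- grid_image(array(rep(0:19, 20), c(20, 20)))
  prob3 <- registration_problem(ramp, ramp, identity_transform(2))
  interior <- as.matrix(expand.grid(5:14, 5:14))
  expect_equal(
    metric_mean_squares(prob3, translation_transform(c(2, 0)), interior),
    4, tolerance = 1e-12)
})

test_that("mutual information equals sampled entropy for an image with itself", {
  img <- make_blob_image(c(24, 24, 24), 1,
                         centers = rbind(c(9, 11, 12), c(15, 13, 11)),
                         sigmas = c(4, 3), amplitudes = c(1, 0.7),
                         noise_sigma = 0.02, seed = 3)
  prob <- registration_problem(img, img, identity_transform(3),
                               metric = "mutual_information", mi_bins = 32L)
  set.seed(1)
  lin <- sample.int(24^3, 6000)
  pts <- index_to_physical(img, arrayInd(lin, rep(24L, 3)) - 1)
  mi <- -metric_mutual_information(prob, identity_transform(3), pts)
  expect_equal(mi, oracle_binned_entropy(img$values[lin], 32L),
               tolerance = 1e-9)
})

test_that("mutual information is near zero for independent images and high under invertible remaps", {
  set.seed(9)
  a <- grid_image(array(runif(40^3), rep(40, 3)))
  b <- grid_image(array(runif(40^3), rep(40, 3)))
  prob <- registration_problem(a, b, identity_transform(3),
                               metric = "mutual_information", mi_bins = 32L)
  lin <- sample.int(40^3, 10000)
  pts <- index_to_physical(a, arrayInd(lin, rep(40L, 3)) - 1)
  expect_lt(-metric_mutual_information(prob, identity_transform(3), pts), 0.1)

  img <- make_blob_image(c(24, 24, 24), 1, centers = matrix(c(12, 11, 13), 1),
                         sigmas = 5, amplitudes = 1, noise_sigma = 0.02, seed = 5)
  flip <- img; flip$values <- max(img$values) + min(img$values) - img$values
  prob2 <- registration_problem(img, flip, identity_transform(3),
                                metric = "mutual_information", mi_bins = 32L)
  set.seed(2)
  lin2 <- sample.int(24^3, 6000)
  pts2 <- index_to_physical(img, arrayInd(lin2, rep(24L, 3)) - 1)
  mi_flip <- -metric_mutual_information(prob2, identity_transform(3), pts2)
  # linear flip preserves equal-width bin contents: MI equals self-MI exactly
  expect_equal(mi_flip, oracle_binned_entropy(img$values[lin2], 32L),
               tolerance = 1e-9)

  # a monotone nonlinear remap keeps MI close to the smaller marginal entropy
  warp <- img; warp$values <- exp(img$values)
  prob3 <- registration_problem(img, warp, identity_transform(3),
                                metric = "mutual_information", mi_bins = 32L)
  mi_warp <- -metric_mutual_information(prob3, identity_transform(3), pts2)
  h_min <- min(oracle_binned_entropy(img$values[lin2], 32L),
               oracle_binned_entropy(warp$values[lin2], 32L))
  expect_gt(mi_warp, 0.8 * h_min)
  expect_error(
    metric_mutual_information(
      registration_problem(grid_image(array(1, c(8, 8, 8))), img,
                           identity_transform(3), metric = "mutual_information",
                           mi_bins = 16L),
      identity_transform(3), pts2),
    class = "ConstantImageError")
})

test_that("physical-shift scales equalize parameter effects", {
  img <- grid_image(array(0, c(101, 101)), spacing = c(1, 1))
  prob <- registration_problem(cast_image(img, "float64"),
                               cast_image(img, "float64"),
                               identity_transform(2))
  tr <- translation_transform(c(0, 0))
  expect_equal(scales_from_physical_shift(prob, tr), c(1, 1), tolerance = 1e-6)

  rig <- rigid_transform(angle = 0, translation = c(0, 0), center = c(50, 50))
  s <- scales_from_physical_shift(prob, rig)
  # the angle scale is the farthest corner's distance from the center
  corner_dist <- max(sqrt(rowSums(sweep(physical_corners(img), 2, c(50, 50))^2)))
  expect_equal(s[1], corner_dist, tolerance = 1e-4)
  expect_equal(s[2:3], c(1, 1), tolerance = 1e-6)
})

test_that("registration requires float pixel kinds", {
  img <- make_blob_image(c(8, 8, 8), 1, centers = matrix(c(4, 4, 4), 1),
                         sigmas = 2, amplitudes = 100)
  ui <- cast_image(img, "uint8")
  prob <- registration_problem(ui, ui, identity_transform(3))
  expect_error(register(prob), class = "PixelKindError")
  expect_error(registration_problem(img, img, identity_transform(3),
                                    sampling_fraction = 0),
               class = "ParameterError")
  expect_error(registration_problem(img, img, identity_transform(3),
                                    schedule = list(c(0, 1))),
               class = "ParameterError")
})

test_that("registration at the optimum stays there and descends elsewhere", {
  img <- make_blob_image(c(24, 24, 24), 1,
                         centers = rbind(c(10, 12, 11), c(15, 11, 13)),
                         sigmas = c(4, 3), amplitudes = c(1, 0.6))
  prob <- registration_problem(img, img, translation_transform(c(0, 0, 0)),
                               metric = "mean_squares", sampling_fraction = 0.2,
                               schedule = list(c(2, 1), c(1, 0)), seed = 3,
                               max_iterations = 40)
  res <- register(prob)
  expect_lt(sqrt(sum(get_parameters(res$t_opt_final)^2)), 0.1)

  # descent property on the trace: the running minimum never increases and
  # the final metric does not exceed the initial one
  tr <- res$metric_trace
  expect_s3_class(tr, "data.frame")
  expect_gt(nrow(tr), 0)
  expect_equal(sort(unique(tr$level)), seq_along(prob$schedule))
  run_min <- cummin(tr$metric)
  expect_true(all(diff(run_min) <= 1e-15))
  expect_lte(res$final_metric, tr$metric[1])
})

test_that("registration is reproducible for a fixed seed", {
  pair <- make_small_pair(sz = 16L)
  mk <- function() registration_problem(
    pair$fixed, pair$moving,
    initialize_geometric_center(pair$fixed, pair$moving, "translation"),
    metric = "mean_squares", sampling_fraction = 1,
    schedule = list(c(2, 1), c(1, 0)), seed = 11, max_iterations = 25)
  r1 <- register(mk()); r2 <- register(mk())
  expect_identical(get_parameters(r1$t_opt_final), get_parameters(r2$t_opt_final))
  expect_identical(r1$metric_trace, r2$metric_trace)
})

test_that("a known translation is recovered on a small pair", {
  truth <- translation_transform(c(2, -1.5, 1))
  pair <- make_small_pair(truth, sz = 32L)
  prob <- registration_problem(
    pair$fixed, pair$moving,
    initialize_geometric_center(pair$fixed, pair$moving, "translation"),
    metric = "mean_squares", sampling_fraction = 0.1,
    schedule = list(c(2, 1), c(1, 0)), seed = 5,
    convergence_tol = 1e-8, max_iterations = 100)
  res <- register(prob)
  # the pair was built by resampling through `truth`, so the registration
  # estimate approximates its inverse
  est <- get_parameters(res$t_opt_final)
  expect_lt(max(abs(est - (-c(2, -1.5, 1)))), 0.2)
})

test_that("the mean-squares optimum sits at the generating shift on a grid of offsets", {
  truth <- translation_transform(c(2, 0, 0))
  pair <- make_small_pair(truth, sz = 16L)
  prob <- registration_problem(pair$fixed, pair$moving, identity_transform(3))
  set.seed(8)
  core <- as.matrix(expand.grid(4:11, 4:11, 4:11))
  pts <- index_to_physical(pair$fixed, core)
  at_truth <- metric_mean_squares(prob, translation_transform(c(-2, 0, 0)), pts)
  for (dx in c(-2, -1, 1, 2)) {
    for (axis in 1:3) {
      off <- c(-2, 0, 0); off[axis] <- off[axis] + dx
      expect_lte(at_truth,
                 metric_mean_squares(prob, translation_transform(off), pts))
    }
  }
})
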