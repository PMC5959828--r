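#' Deterministic synthetic fixtures
#'
#' Generators that make every other module testable without any external
#' data: smooth multi-blob images, mono-/multi-modal registration pairs
#' related by a known transform, multi-rater binary segmentations with known
#' per-rater sensitivity/specificity, and volumes containing a single bright
#' spherical fiducial.  All randomness flows through an explicit `seed`
#' argument; the caller's RNG state is left untouched.
#'
#' @name fixtures
NULL

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sum-of-Gaussian-blobs image
#'
#' @param size Integer d-vector of voxel counts.
#' @param spacing Numeric d-vector, mm.
#' @param centers n x d matrix of blob centers (physical mm).
#' @param sigmas Length-n vector of blob widths, mm.
#' @param amplitudes Length-n vector of peak intensities.
#' @param noise_sigma Additive Gaussian noise standard deviation (0 = none).
#' @param seed Integer seed for the noise.
#' @param origin,direction Grid metadata (defaults: 0 / identity).
#' @return A float64 `grid_image`.
#' @export
make_blob_image <- function(size, spacing = NULL, centers, sigmas, amplitudes,
                            noise_sigma = 0, seed = 1L,
                            origin = NULL, direction = NULL) {
  size <- as.integer(size)
  d <- length(size)
  spacing <- if (is.null(spacing)) rep(1, d) else rep(spacing, length.out = d)
  img <- grid_image(array(0, size), origin = origin, spacing = spacing,
                    direction = direction, pixel_kind = "float64")
  centers <- matrix(centers, ncol = d)
  pts <- index_to_physical(img, grid_index_matrix(size))
  v <- numeric(nrow(pts))
  for (b in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(pts, 2L, centers[b, ], `-`)^2)
    v <- v + amplitudes[b] * exp(-d2 / (2 * sigmas[b]^2))
  }
  if (noise_sigma > 0) {
    v <- v + with_local_seed(seed, stats::rnorm(length(v), 0, noise_sigma))
  }
  img$values <- array(v, size)
  img
}

default_registration_base <- function(size = c(64L, 64L, 64L), spacing = 1,
                                      noise_sigma = 0.005, seed = 20L) {
  ext <- (size - 1) * rep(spacing, length.out = length(size))
  centers <- rbind(ext * c(0.38, 0.45, 0.47),
                   ext * c(0.63, 0.57, 0.46),
                   ext * c(0.50, 0.50, 0.68),
                   ext * c(0.42, 0.64, 0.58))
  make_blob_image(size, spacing, centers,
                  sigmas = c(0.10, 0.085, 0.07, 0.055) * max(ext),
                  amplitudes = c(1, 0.75, 0.6, 0.5),
                  noise_sigma = noise_sigma, seed = seed)
}

#' Registration pair with known ground truth
#'
#' The fixed image is a smooth asymmetric multi-blob volume; the moving
#' image is the fixed image resampled through `truth` (so `truth` is the
#' map from fixed-frame points to the points whose fixed-image intensity
#' the moving image shows) and then optionally intensity-remapped to
#' emulate a second modality.  Registration of the pair therefore recovers
#' the *inverse* of `truth`; compose the estimate with `truth` and compare
#' to the identity to measure the recovery error.
#'
#' @param truth A matrix-offset transform (must be invertible).
#' @param intensity_remap `"identity"`, `"invert"` (linear intensity flip)
#'   or `"log"` (monotone compressive remap).
#' @param size,spacing,noise_sigma,seed Passed to the blob generator.
#' @return A list with elements `fixed`, `moving`, `truth`.
#' @export
make_registration_pair <- function(truth,
                                   intensity_remap = c("identity", "invert", "log"),
                                   size = c(64L, 64L, 64L), spacing = 1,
                                   noise_sigma = 0.005, seed = 20L) {
  intensity_remap <- match.arg(intensity_remap)
  invert_transform(truth)  # errors early if singular
  fixed <- default_registration_base(size, spacing, noise_sigma, seed)
  moving <- resample(fixed, fixed, truth, interpolator = "linear")
  rng <- range(fixed$values)
  moving$values <- switch(intensity_remap,
    identity = moving$values,
    invert = rng[2] + rng[1] - moving$values,
    log = log1p(pmax(moving$values - rng[1], 0))
  )
  list(fixed = fixed, moving = moving, truth = truth)
}

#' Simulated rater stack for consensus-segmentation recovery
#'
#' Each rater marks a true foreground voxel with probability `sensitivity`
#' and a true background voxel with probability `1 - specificity`,
#' independently per voxel — the generative model under which STAPLE's
#' per-rater performance estimates are consistent.
#'
#' @param truth_mask A binary `grid_image` (values 0/1).
#' @param n_raters Number of raters.
#' @param sensitivity,specificity Per-rater true-positive / true-negative
#'   rates in (0, 1].
#' @param seed Integer seed.
#' @return List of `n_raters` binary `grid_image`s.
#' @export
make_rater_stack <- function(truth_mask, n_raters, sensitivity, specificity,
                             seed = 1L) {
  stopifnot(sensitivity > 0, sensitivity <= 1, specificity > 0, specificity <= 1)
  truth <- truth_mask$values > 0.5
  n <- length(truth)
  with_local_seed(seed, {
    lapply(seq_len(n_raters), function(j) {
      u <- stats::runif(n)
      v <- ifelse(truth, u < sensitivity, u > specificity) + 0
      out <- truth_mask
      out$values <- array(v, dim(truth_mask$values))
      out$pixel_kind <- "label"
      out
    })
  })
}

#' Digitized sphere mask
#'
#' Foreground where the voxel center lies within `radius` of `center`.
#'
#' @param size,spacing,origin,direction Grid metadata.
#' @param center Sphere center, physical mm.
#' @param radius Sphere radius, mm.
#' @return A binary `grid_image` (pixel kind `label`).
#' @export
make_sphere_mask <- function(size, spacing = NULL, center, radius,
                             origin = NULL, direction = NULL) {
  size <- as.integer(size)
  d <- length(size)
  spacing <- if (is.null(spacing)) rep(1, d) else rep(spacing, length.out = d)
  img <- grid_image(array(0, size), origin = origin, spacing = spacing,
                    direction = direction, pixel_kind = "label")
  pts <- index_to_physical(img, grid_index_matrix(size))
  inside <- rowSums(sweep(pts, 2L, center, `-`)^2) <= radius^2
  img$values <- array(inside + 0, size)
  img
}

#' Volume containing a single bright spherical fiducial
#'
#' Background level plus `contrast` inside the digitized sphere, plus
#' optional Gaussian noise.
#'
#' @inheritParams make_sphere_mask
#' @param background Background intensity.
#' @param contrast Added intensity inside the sphere.
#' @param noise_sigma Gaussian noise sd.
#' @param seed Integer seed.
#' @return A float64 `grid_image`.
#' @export
make_fiducial_volume <- function(size, spacing = NULL, center, radius,
                                 background = 10, contrast = 100,
                                 noise_sigma = 0, seed = 1L,
                                 origin = NULL, direction = NULL) {
  size <- as.integer(size)
  d <- length(size)
  spacing <- if (is.null(spacing)) rep(1, d) else rep(spacing, length.out = d)
  probe <- grid_image(array(0, size), origin = origin, spacing = spacing,
                      direction = direction)
  lo <- index_to_physical(probe, rep(0, d))
  hi <- index_to_physical(probe, size - 1)
  if (any(center - radius < pmin(lo, hi)) || any(center + radius > pmax(lo, hi))) {
    pg_stop("BoundsError", "fiducial sphere extends outside the volume")
  }
  mask <- make_sphere_mask(size, spacing, center, radius, origin, direction)
  v <- background + contrast * mask$values
  if (noise_sigma > 0) {
    v <- v + with_local_seed(seed,
           array(stats::rnorm(length(v), 0, noise_sigma), dim(v)))
  }
  out <- mask
  out$values <- v
  out$pixel_kind <- "float64"
  out
}
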