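# Grid interpolation and separable filtering primitives.
#
# All continuous indexes here are zero-based (voxel centers, ITK
# convention); conversion to R's one-based arrays happens in the linear
# index arithmetic below.

# d-linear interpolation of `arr` at an n x d matrix of continuous indexes.
# Out-of-range corner samples contribute zero (zero padding), which is the
# documented behaviour for displacement fields near the domain edge.
interp_array_linear <- function(arr, idx, pad_zero = TRUE) {
  dims <- dim(arr)
  d <- length(dims)
  n <- nrow(idx)
  f <- floor(idx)
  w <- idx - f
  strides <- cumprod(c(1, dims[-d]))
  out <- numeric(n)
  for (corner in seq_len(2L^d) - 1L) {
    bits <- as.integer(intToBits(corner))[seq_len(d)]
    wt <- rep(1, n)
    lin <- rep(1, n)
    ok <- rep(TRUE, n)
    for (k in seq_len(d)) {
      ik <- f[, k] + bits[k]
      wt <- wt * if (bits[k] == 1L) w[, k] else 1 - w[, k]
      ok <- ok & ik >= 0 & ik <= dims[k] - 1
      lin <- lin + pmin(pmax(ik, 0), dims[k] - 1) * strides[k]
    }
    vals <- arr[lin]
    vals[!ok] <- 0
    out <- out + wt * vals
  }
  out
}

# Nearest-neighbour lookup; ties at half-way points break toward the lower
# index.  Indexes are clamped, validity is reported separately.
interp_array_nearest <- function(arr, idx) {
  dims <- dim(arr)
  d <- length(dims)
  strides <- cumprod(c(1, dims[-d]))
  lin <- rep(1, nrow(idx))
  for (k in seq_len(d)) {
    ik <- pmin(pmax(ceiling(idx[, k] - 0.5), 0), dims[k] - 1)
    lin <- lin + ik * strides[k]
  }
  arr[lin]
}

# Sample an image's value array at continuous indexes; returns values plus a
# validity mask (inside the interpolator's support).  Linear support is the
# voxel-center hull [0, size-1]; nearest support is the physical extent
# [-1/2, size-1/2].
sample_at_index <- function(values, idx, interpolator = c("linear", "nearest")) {
  interpolator <- match.arg(interpolator)
  dims <- dim(values)
  valid <- rep(TRUE, nrow(idx))
  if (interpolator == "linear") {
    for (k in seq_along(dims)) {
      valid <- valid & idx[, k] >= 0 & idx[, k] <= dims[k] - 1
    }
    vals <- interp_array_linear(values, idx)
  } else {
    for (k in seq_along(dims)) {
      valid <- valid & idx[, k] >= -0.5 & idx[, k] <= dims[k] - 0.5
    }
    vals <- interp_array_nearest(values, idx)
  }
  list(values = vals, valid = valid)
}

# Convolve along one axis with a 1-D kernel, renormalizing at the borders
# so constant images stay constant.
conv_axis <- function(arr, kernel, axis) {
  dims <- dim(arr)
  d <- length(dims)
  perm <- c(axis, seq_len(d)[-axis])
  a <- aperm(arr, perm)
  pd <- dim(a)
  m <- matrix(a, nrow = pd[1])
  n <- pd[1]
  r <- (length(kernel) - 1L) %/% 2L
  acc <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(kernel)) {
    shift <- j - 1L - r
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + kernel[j] * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + kernel[j]
  }
  acc <- acc / wsum
  out <- array(acc, pd)
  aperm(out, order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing in physical units
#'
#' Separable discrete Gaussian; `sigma` is given in mm and converted to
#' voxels through the image spacing, so smoothing is isotropic in physical
#' space even on anisotropic grids.  `sigma = 0` is a no-op.
#'
#' @param img A `grid_image`.
#' @param sigma Scalar or d-vector smoothing sigma, mm.
#' @return A smoothed `grid_image` (same grid and metadata).
#' @export
gaussian_smooth <- function(img, sigma) {
  d <- image_ndim(img)
  sigma <- rep(as.numeric(sigma), length.out = d)
  v <- img$values
  for (k in seq_len(d)) {
    sv <- sigma[k] / img$spacing[k]
    if (sv > 1e-8) v <- conv_axis(v, gaussian_kernel(sv), k)
  }
  out <- img
  out$values <- v
  out
}

#' Shrink an image by integer block subsampling
#'
#' Keeps every `factor`-th voxel starting from the first, multiplies the
#' spacing by `factor` and preserves the origin at the first voxel center.
#' Pair with [gaussian_smooth()] to build a multi-resolution pyramid.
#'
#' @param img A `grid_image`.
#' @param factor Integer >= 1 (scalar or d-vector).
#' @return The shrunk `grid_image`.
#' @export
shrink_image <- function(img, factor) {
  d <- image_ndim(img)
  factor <- rep(as.integer(factor), length.out = d)
  if (any(factor < 1L)) pg_stop("ParameterError", "shrink factor must be >= 1")
  if (all(factor == 1L)) return(img)
  sz <- image_size(img)
  ranges <- lapply(seq_len(d), function(k) seq.int(1L, sz[k], by = factor[k]))
  out <- img
  out$values <- do.call(`[`, c(list(img$values), ranges, list(drop = FALSE)))
  out$spacing <- img$spacing * factor
  out
}
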