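#' Otsu threshold selection
#'
#' Builds an `n_bins` equal-width histogram of the image intensities and
#' returns the cut maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`.  The threshold is reported as the *upper
#' edge* of the chosen bin; foreground is `values > threshold`.
#'
#' @param img A `grid_image` (or numeric vector/array) with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold (numeric scalar).
#' @export
otsu_threshold <- function(img, n_bins = 128L) {
  x <- if (is_grid_image(img)) as.numeric(img$values) else as.numeric(img)
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    pg_stop("ConstantImageError", "constant image has no Otsu threshold")
  }
  h <- bin_counts(x, r, n_bins)
  k <- which.max(between_class_variance(h$counts, h$mids))
  r[1] + k * (r[2] - r[1]) / n_bins
}

bin_counts <- function(x, r, n_bins) {
  u <- (x - r[1]) / (r[2] - r[1]) * n_bins
  b <- pmin(pmax(ceiling(u), 1L), n_bins)  # values at the minimum fall in bin 1
  width <- (r[2] - r[1]) / n_bins
  list(counts = tabulate(b, n_bins),
       mids = r[1] + (seq_len(n_bins) - 0.5) * width)
}

# Between-class variance for every cut k (class 0 = bins 1..k); NA where a
# class is empty.
between_class_variance <- function(counts, mids) {
  n <- sum(counts)
  csum <- cumsum(counts)
  cmu <- cumsum(counts * mids)
  total_mu <- cmu[length(cmu)]
  k <- seq_len(length(counts) - 1L)
  w0 <- csum[k] / n
  w1 <- 1 - w0
  mu0 <- cmu[k] / csum[k]
  mu1 <- (total_mu - cmu[k]) / (n - csum[k])
  v <- w0 * w1 * (mu0 - mu1)^2
  v[csum[k] == 0 | csum[k] == n] <- NA_real_
  v
}

#' Box-shaped region of interest
#'
#' @param start Zero-based integer d-vector.
#' @param size Integer d-vector of voxel counts.
#' @return A `box_roi` object.
#' @export
box_roi <- function(start, size) {
  structure(list(start = as.integer(round(start)),
                 size = as.integer(round(size))),
            class = "box_roi")
}

#' Centroid and equivalent-sphere radius of a segmented blob
#'
#' Location is the mean of the foreground voxels' physical coordinates;
#' the radius is that of the sphere with the same volume as the blob,
#' `(3 V / 4 pi)^(1/3)` with `V = count * voxel volume` (anisotropic
#' spacing handled through the voxel volume).  The RMS residual is 0 by
#' convention for this path.
#'
#' @param mask A non-empty binary `grid_image`.
#' @return A `sphere_fit`: list with `center` (mm), `radius` (mm),
#'   `rms_residual` (mm), `n_points`.
#' @export
blob_centroid_radius <- function(mask) {
  m <- as_logical_mask(mask)
  if (!any(m)) pg_stop("DegenerateInputError", "mask is empty")
  idx0 <- arrayInd(which(m), dim(m)) - 1L
  pts <- index_to_physical(mask, idx0)
  vol <- sum(m) * prod(mask$spacing)
  new_sphere_fit(colMeans(pts), (3 * vol / (4 * pi))^(1 / 3), 0, sum(m))
}

new_sphere_fit <- function(center, radius, rms, n) {
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = rms, n_points = as.integer(n)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: center (%s) mm, radius %.4f mm, rms %.4g mm (n=%d)\n",
              paste(sprintf("%.4f", x$center), collapse = ", "),
              x$radius, x$rms_residual, x$n_points))
  invisible(x)
}

#' Edge detection (Canny-style, 2-D/3-D)
#'
#' Gaussian smoothing at `sigma` (mm), central-difference intensity
#' gradient in physical units, non-maximum suppression of the gradient
#' magnitude along the gradient direction (magnitude linearly interpolated
#' one voxel step either way), then hysteresis: voxels above `high`
#' survive, plus any voxel above `low` face-connected to a surviving
#' voxel.  No sub-voxel refinement is applied.
#'
#' @param img A `grid_image`.
#' @param sigma Smoothing sigma, mm.
#' @param low,high Hysteresis thresholds on gradient magnitude
#'   (intensity/mm), `low < high`.
#' @return n x d matrix of edge-voxel physical coordinates (mm).
#' @export
detect_edges <- function(img, sigma = 1, low, high) {
  if (low >= high) pg_stop("ParameterError", "need low < high")
  sm <- gaussian_smooth(img, sigma)
  g <- image_gradient(sm)
  mag <- sqrt(Reduce(`+`, lapply(g, `^`, 2)))
  d <- image_ndim(img)
  cand <- which(mag > low)
  if (!length(cand)) {
    pg_stop("EmptyResultError", "no gradient magnitude above the low threshold")
  }
  idx0 <- arrayInd(cand, dim(mag)) - 1L
  gm <- mag[cand]
  dirm <- vapply(g, `[`, numeric(length(cand)), cand)
  dirm <- dirm / pmax(gm, 1e-12)
  # step is one voxel in index space along the gradient direction
  step_idx <- sweep(dirm, 2L, img$spacing, `/`)
  step_idx <- step_idx / pmax(sqrt(rowSums(step_idx^2)), 1e-12)
  m_fwd <- interp_array_linear(mag, idx0 + step_idx)
  m_bwd <- interp_array_linear(mag, idx0 - step_idx)
  keep <- gm >= m_fwd & gm >= m_bwd
  nms <- array(FALSE, dim(mag))
  nms[cand[keep]] <- TRUE
  strong <- array(FALSE, dim(mag))
  strong[cand[keep][gm[keep] > high]] <- TRUE
  if (!any(strong)) pg_stop("EmptyResultError", "no edges above the high threshold")
  labels <- label_components(nms, "face")
  good <- unique(labels[strong])
  final <- nms & array(labels %in% good, dim(labels))
  edge_idx <- arrayInd(which(final), dim(mag)) - 1L
  index_to_physical(img, edge_idx)
}

# Central-difference gradient per axis, in intensity per mm (one-sided at
# the borders).
image_gradient <- function(img) {
  v <- img$values
  d <- image_ndim(img)
  lapply(seq_len(d), function(k) {
    fwd <- shift_array(v, k, -1L, fill = NA)   # value at i+1
    bwd <- shift_array(v, k, 1L, fill = NA)    # value at i-1
    g <- (fwd - bwd) / (2 * img$spacing[k])
    one_f <- (fwd - v) / img$spacing[k]
    one_b <- (v - bwd) / img$spacing[k]
    g[is.na(g) & !is.na(fwd)] <- one_f[is.na(g) & !is.na(fwd)]
    g[is.na(g) & !is.na(bwd)] <- one_b[is.na(g) & !is.na(bwd)]
    g[is.na(g)] <- 0
    g
  })
}

#' Least-squares sphere fit
#'
#' Algebraic linear least squares first: solving
#' `[2 x_i', 1] [c; b] = |x_i|^2` for the center `c` and `b = r^2 - |c|^2`.
#' When `refine = TRUE` (default) the algebraic estimate seeds a
#' Gauss-Newton minimization of the geometric residuals
#' `(|x_i - c| - r)^2`.  Coplanar or otherwise rank-deficient point sets
#' raise `SingularFitError`.
#'
#' @param points n x d matrix of physical points (mm), n >= d + 2.
#' @param refine Run the geometric refinement?
#' @return A `sphere_fit` (see [blob_centroid_radius()]); `rms_residual`
#'   is the root-mean-square geometric residual.
#' @export
fit_sphere <- function(points, refine = TRUE) {
  pts <- as.matrix(points)
  d <- ncol(pts)
  n <- nrow(pts)
  if (n < d + 2L) {
    pg_stop("SingularFitError",
            sprintf("need at least %d points for a %d-D sphere fit", d + 2L, d))
  }
  X <- cbind(2 * pts, 1)
  y <- rowSums(pts^2)
  qr_x <- qr(X)
  if (qr_x$rank < d + 1L ||
      min(abs(diag(qr.R(qr_x)))) < 1e-10 * max(abs(diag(qr.R(qr_x))))) {
    pg_stop("SingularFitError",
            "points are coplanar/degenerate; sphere fit is rank deficient")
  }
  beta <- qr.coef(qr_x, y)
  ctr <- beta[seq_len(d)]
  r2 <- beta[d + 1L] + sum(ctr^2)
  if (r2 <= 0) pg_stop("SingularFitError", "algebraic fit yields non-positive radius")
  r <- sqrt(r2)
  if (refine) {
    for (it in seq_len(50L)) {
      diff <- sweep(pts, 2L, ctr, `-`)
      dist <- sqrt(rowSums(diff^2))
      res <- dist - r
      Jm <- cbind(-diff / pmax(dist, 1e-12), -1)
      upd <- tryCatch(qr.coef(qr(Jm), -res), error = function(e) NULL)
      if (is.null(upd) || any(!is.finite(upd))) break
      ctr <- ctr + upd[seq_len(d)]
      r <- r + upd[d + 1L]
      if (max(abs(upd)) < 1e-12) break
    }
  }
  dist <- sqrt(rowSums(sweep(pts, 2L, ctr, `-`)^2))
  new_sphere_fit(ctr, r, sqrt(mean((dist - r)^2)), n)
}

#' Localize a spherical fiducial inside a region of interest
#'
#' Crops the box ROI (the crop keeps world coordinates, so results are
#' reported in the full image's physical frame) and runs one of two
#' pipelines: `"otsu"` — Otsu threshold, largest connected component,
#' centroid + equivalent-sphere radius; `"edge"` — Canny-style edge
#' detection followed by a least-squares sphere fit.
#'
#' @param img A `grid_image` containing a single bright spherical fiducial
#'   within the ROI.
#' @param roi A [box_roi()].
#' @param method `"otsu"` or `"edge"`.
#' @param sigma Edge-detection smoothing, mm (edge method).
#' @param low,high Optional hysteresis thresholds; defaults are `high =
#'   0.5 * max` gradient magnitude in the ROI and `low = 0.5 * high`.
#' @return A `sphere_fit` in the full image's physical frame.
#' @export
localize_fiducial <- function(img, roi, method = c("otsu", "edge"),
                              sigma = 1, low = NULL, high = NULL) {
  method <- match.arg(method)
  crop <- extract_region(img, roi$start, roi$size)
  if (method == "otsu") {
    thr <- otsu_threshold(crop)
    mask <- crop
    mask$values <- array((crop$values > thr) + 0, dim(crop$values))
    mask$pixel_kind <- "label"
    if (!any(mask$values > 0)) {
      pg_stop("DegenerateInputError", "Otsu segmentation is empty inside the ROI")
    }
    blob_centroid_radius(largest_component(mask))
  } else {
    if (is.null(high) || is.null(low)) {
      g <- image_gradient(gaussian_smooth(crop, sigma))
      mx <- max(sqrt(Reduce(`+`, lapply(g, `^`, 2))))
      # guard against a (near-)constant ROI: smoothing round-off must not
      # masquerade as edges
      if (mx <= 1e-8 * max(1, max(abs(crop$values)))) {
        pg_stop("EmptyResultError", "no intensity gradients inside the ROI")
      }
      if (is.null(high)) high <- 0.5 * mx
      if (is.null(low)) low <- 0.5 * high
    }
    pts <- detect_edges(crop, sigma, low, high)
    fit_sphere(pts, refine = TRUE)
  }
}
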