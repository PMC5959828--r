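#' Resample an image onto a reference grid through a transform
#'
#' For every voxel `i` of the reference grid the physical point
#' `p = index_to_physical(reference, i)` is mapped through `transform`
#' (which points from the *reference* frame into the *moving* frame, as in
#' registration) and the moving image is interpolated there.  Points that
#' fall outside the moving image's support receive `default_value`.  The
#' output carries the reference grid's metadata exactly — resampling is how
#' an image is re-expressed on another physical grid, so origin, spacing
#' and direction come from the reference, never from the input intensities.
#'
#' @param moving `grid_image` supplying the intensities.
#' @param reference `grid_image` supplying the output grid (its values are
#'   ignored).
#' @param transform A spatial transform mapping reference-frame points into
#'   the moving frame.  Default: identity.
#' @param interpolator `"linear"` (default) or `"nearest"` (half-way ties
#'   toward the lower index).
#' @param default_value Value for out-of-support points.  Default 0.
#' @return A `grid_image` on the reference grid.
#' @export
resample <- function(moving, reference, transform = NULL,
                     interpolator = c("linear", "nearest"),
                     default_value = 0) {
  interpolator <- match.arg(interpolator)
  transform <- transform %||% identity_transform(image_ndim(moving))
  sz <- image_size(reference)
  idx <- grid_index_matrix(sz)
  p <- index_to_physical(reference, idx)
  p <- apply_transform(transform, p)
  midx <- physical_to_index(moving, p)
  s <- sample_at_index(moving$values, midx, interpolator)
  vals <- s$values
  vals[!s$valid] <- default_value
  out <- reference
  out$values <- array(vals, sz)
  out$pixel_kind <- moving$pixel_kind
  out$values <- clamp_values(out$values, out$pixel_kind)
  out
}

# All zero-based grid indexes of a grid of size `sz`, as a (prod(sz) x d)
# matrix in column-major (first axis fastest) order.
grid_index_matrix <- function(sz) {
  d <- length(sz)
  idx <- matrix(0, prod(sz), d)
  rep_each <- 1L
  for (k in seq_len(d)) {
    idx[, k] <- rep(rep(0:(sz[k] - 1L), each = rep_each),
                    length.out = prod(sz))
    rep_each <- rep_each * sz[k]
  }
  idx
}

#' Resample an image onto an isotropic grid
#'
#' The output keeps the input's origin and axis directions but uses spacing
#' `iso_spacing` on every axis.  The per-axis voxel count is
#' `max(1, round(size * spacing / iso_spacing))`, chosen so the resampled
#' image occupies the same physical region in space as the original to
#' within one voxel.
#'
#' @param img A `grid_image`.
#' @param iso_spacing Target spacing, mm (> 0).
#' @param interpolator Passed to [resample()].
#' @param default_value Passed to [resample()].
#' @return An isotropically sampled `grid_image`.
#' @export
resample_isotropic <- function(img, iso_spacing,
                               interpolator = c("linear", "nearest"),
                               default_value = 0) {
  if (iso_spacing <= 0) pg_stop("ParameterError", "iso_spacing must be > 0")
  resample_to_spacing(img, rep(iso_spacing, image_ndim(img)),
                      interpolator, default_value)
}

resample_to_spacing <- function(img, new_spacing,
                                interpolator = c("linear", "nearest"),
                                default_value = 0) {
  sz <- image_size(img)
  new_size <- pmax(1L, as.integer(round(sz * img$spacing / new_spacing)))
  ref <- grid_image(array(0, new_size), origin = img$origin,
                    spacing = new_spacing, direction = img$direction,
                    pixel_kind = img$pixel_kind)
  resample(img, ref, identity_transform(image_ndim(img)),
           interpolator = interpolator, default_value = default_value)
}
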