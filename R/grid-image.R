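#' Physically grounded scalar images
#'
#' A `grid_image` is a d-dimensional scalar voxel grid (d = 2 or 3) together
#' with the metadata that anchors it in physical space: an origin (mm), a
#' per-axis spacing (mm, strictly positive) and an orthonormal direction
#' cosine matrix whose columns give the physical direction of each image
#' axis.  Images are never bare arrays: every operation in this package that
#' combines two images first checks that they occupy the same physical
#' region, and resampling/registration work in physical coordinates
#' throughout.
#'
#' Grid indexes exposed by this API are **zero-based** and refer to voxel
#' centers (the ITK convention), so index `(0, 0)` maps exactly to the
#' origin.  This differs from R's one-based array indexing; conversion
#' happens internally.  The physical extent of an image spans index
#' `[-1/2, size - 1/2]` along each axis, i.e. half a voxel beyond the first
#' and last voxel centers.
#'
#' @param values Numeric array with `length(dim(values))` equal to 2 or 3.
#' @param origin Numeric d-vector, mm.  Default all zeros.
#' @param spacing Numeric d-vector, mm, each component > 0.  Default 1.
#' @param direction d x d orthonormal matrix.  Default identity.  A
#'   non-orthonormal matrix is rejected rather than silently orthogonalized.
#' @param pixel_kind One of `"float64"`, `"float32"`, `"uint8"`, `"int32"`,
#'   `"label"`.  Values are stored as R doubles; the tag governs casting and
#'   file I/O element types.
#' @return An object of class `grid_image`.
#' @examples
#' img <- grid_image(array(0, c(4, 4)), origin = c(10, 20), spacing = c(2, 3))
#' index_to_physical(img, c(1, 1))  # c(12, 23)
#' @export
grid_image <- function(values, origin = NULL, spacing = NULL,
                       direction = NULL, pixel_kind = "float64") {
  if (is.null(dim(values))) dim(values) <- length(values)
  d <- length(dim(values))
  if (!d %in% c(2L, 3L)) {
    pg_stop("ShapeError", sprintf("grid_image supports 2-D and 3-D grids, got %d-D", d))
  }
  origin <- if (is.null(origin)) rep(0, d) else as.numeric(origin)
  spacing <- if (is.null(spacing)) rep(1, d) else as.numeric(spacing)
  direction <- if (is.null(direction)) diag(d) else as.matrix(direction)
  if (length(origin) != d || length(spacing) != d ||
      !all(dim(direction) == c(d, d))) {
    pg_stop("ShapeError", "origin/spacing/direction dimensions do not match the value grid")
  }
  if (any(!is.finite(origin)) || any(!is.finite(spacing)) || any(!is.finite(direction))) {
    pg_stop("ShapeError", "image metadata must be finite")
  }
  if (any(spacing <= 0)) {
    pg_stop("ShapeError", "spacing components must be strictly positive")
  }
  if (max(abs(crossprod(direction) - diag(d))) > 1e-6) {
    pg_stop("ShapeError", "direction matrix must be orthonormal (within 1e-6)")
  }
  pixel_kind <- match.arg(pixel_kind,
                          c("float64", "float32", "uint8", "int32", "label"))
  structure(
    list(values = clamp_values(values, pixel_kind),
         origin = origin, spacing = spacing, direction = direction,
         pixel_kind = pixel_kind),
    class = "grid_image"
  )
}

#' @export
print.grid_image <- function(x, ...) {
  cat(sprintf("grid_image: %s voxels, pixel_kind %s\n",
              paste(dim(x$values), collapse = " x "), x$pixel_kind))
  cat("  origin :", paste(signif(x$origin, 6), collapse = ", "), "mm\n")
  cat("  spacing:", paste(signif(x$spacing, 6), collapse = ", "), "mm\n")
  cat("  direction:\n")
  print(signif(x$direction, 6))
  invisible(x)
}

#' @rdname grid_image
#' @param x Object to test.
#' @export
is_grid_image <- function(x) inherits(x, "grid_image")

#' Image size (voxel counts per axis)
#' @param img A `grid_image`.
#' @return Integer vector of per-axis voxel counts.
#' @export
image_size <- function(img) dim(img$values)

image_ndim <- function(img) length(dim(img$values))

clamp_values <- function(values, pixel_kind) {
  v <- values
  storage.mode(v) <- "double"
  switch(pixel_kind,
    uint8 = ,
    label = array(pmin(pmax(round(v), 0), 255), dim(v)),
    int32 = array(pmin(pmax(round(v), -2147483647), 2147483647), dim(v)),
    # float32 images hold single-precision values: quantize once here so
    # that arithmetic, casting and file round trips are all self-consistent
    float32 = array(readBin(writeBin(as.numeric(v), raw(), size = 4L),
                            "double", n = length(v), size = 4L), dim(v)),
    float64 = v
  )
}

#' Map a (continuous, zero-based) grid index to a physical point
#'
#' Computes `origin + direction %*% (spacing * idx)`.  The index may be
#' fractional and may lie outside the grid; the mapping is linear everywhere.
#'
#' @param img A `grid_image`.
#' @param idx Numeric d-vector (one index) or an n x d matrix of indexes,
#'   zero-based.
#' @return A numeric d-vector, or an n x d matrix when `idx` is a matrix.
#' @export
index_to_physical <- function(img, idx) {
  if (is.matrix(idx)) {
    scaled <- sweep(idx, 2L, img$spacing, `*`)
    sweep(scaled %*% t(img$direction), 2L, img$origin, `+`)
  } else {
    as.numeric(img$origin + img$direction %*% (img$spacing * as.numeric(idx)))
  }
}

#' Map a physical point to a continuous (zero-based) grid index
#'
#' Exact inverse of [index_to_physical()]; for orthonormal directions the
#' inverse of the direction matrix is its transpose.
#'
#' @param img A `grid_image`.
#' @param p Numeric d-vector or n x d matrix of physical points, mm.
#' @return Continuous zero-based index (vector or matrix, matching `p`).
#' @export
physical_to_index <- function(img, p) {
  if (is.matrix(p)) {
    centered <- sweep(p, 2L, img$origin, `-`)
    sweep(centered %*% img$direction, 2L, img$spacing, `/`)
  } else {
    as.numeric(crossprod(img$direction, as.numeric(p) - img$origin) / img$spacing)
  }
}

#' Do two images occupy the same physical space?
#'
#' True iff the grids have identical sizes and their origin, spacing and
#' direction agree within `tol` per component (absolute).  The default
#' tolerance of 1e-6 mm matches typical scanner metadata precision.
#'
#' @param a,b `grid_image` objects.
#' @param tol Absolute per-component tolerance, mm.
#' @return Logical scalar.
#' @export
same_physical_space <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    length(a$origin) == length(b$origin) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Pixelwise arithmetic between spatially coincident images
#'
#' Combines two images elementwise.  Following the physical-image tenet,
#' this is only legal when both images occupy the same physical space;
#' otherwise a `SpatialMismatchError` is raised — the operation is never
#' silently broadcast over mismatched grids.
#'
#' @param a,b `grid_image` objects occupying the same physical space.
#' @param op One of `"add"`, `"sub"`, `"mul"`, `"compare"` (`compare` yields
#'   a 0/1 equality mask).
#' @param tol Tolerance forwarded to [same_physical_space()].
#' @return A `grid_image` carrying `a`'s metadata.
#' @export
pixelwise_binary <- function(a, b, op = c("add", "sub", "mul", "compare"),
                             tol = 1e-6) {
  op <- match.arg(op)
  if (!same_physical_space(a, b, tol)) {
    pg_stop("SpatialMismatchError",
            "images do not occupy the same physical space; pixelwise operations are illegal")
  }
  v <- switch(op,
    add = a$values + b$values,
    sub = a$values - b$values,
    mul = a$values * b$values,
    compare = (a$values == b$values) + 0
  )
  out <- a
  out$values <- clamp_values(v, a$pixel_kind)
  out
}

#' @export
Ops.grid_image <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") { e1$values <- -e1$values; return(e1) }
    stop("unary ", .Generic, " not supported for grid_image")
  }
  if (is_grid_image(e1) && is_grid_image(e2)) {
    op <- switch(.Generic, "+" = "add", "-" = "sub", "*" = "mul",
                 "==" = "compare",
                 stop(.Generic, " not supported between grid_images"))
    return(pixelwise_binary(e1, e2, op))
  }
  img <- if (is_grid_image(e1)) e1 else e2
  other <- if (is_grid_image(e1)) e2 else e1
  v <- if (is_grid_image(e1)) get(.Generic)(e1$values, other)
       else get(.Generic)(other, e2$values)
  img$values <- clamp_values(v, img$pixel_kind)
  img
}

#' Extract a rectangular sub-region, staying in world coordinates
#'
#' The crop's origin is the physical point of the region's first voxel, so
#' the sub-image occupies exactly the physical region it did inside the
#' parent image; spacing and direction are preserved.
#'
#' @param img A `grid_image`.
#' @param start Zero-based integer d-vector: first voxel of the region.
#' @param size Integer d-vector of voxel counts, all >= 1.
#' @return A `grid_image` covering the requested region.
#' @export
extract_region <- function(img, start, size) {
  d <- image_ndim(img)
  start <- as.integer(round(start)); size <- as.integer(round(size))
  if (length(start) != d || length(size) != d) {
    pg_stop("BoundsError", "start/size length must match image dimension")
  }
  if (any(size < 1L) || any(start < 0L) || any(start + size > image_size(img))) {
    pg_stop("BoundsError", sprintf(
      "region [start %s, size %s] outside image of size %s",
      paste(start, collapse = ","), paste(size, collapse = ","),
      paste(image_size(img), collapse = ",")))
  }
  ranges <- lapply(seq_len(d), function(k) seq.int(start[k] + 1L, start[k] + size[k]))
  vals <- do.call(`[`, c(list(img$values), ranges, list(drop = FALSE)))
  out <- img
  out$values <- vals
  out$origin <- index_to_physical(img, start)
  out
}

#' Convert pixel kind
#'
#' Metadata is preserved.  Narrowing integer casts clamp (e.g. 300 ->
#' 255 for `uint8`) and round; widening casts are exact.
#'
#' @param img A `grid_image`.
#' @param pixel_kind Target pixel kind (see [grid_image()]).
#' @return A `grid_image` with the requested pixel kind.
#' @export
cast_image <- function(img, pixel_kind) {
  pixel_kind <- match.arg(pixel_kind,
                          c("float64", "float32", "uint8", "int32", "label"))
  if (identical(pixel_kind, img$pixel_kind)) return(img)
  out <- img
  out$pixel_kind <- pixel_kind
  out$values <- clamp_values(img$values, pixel_kind)
  out
}

#' Move voxel values to and from plain arrays
#'
#' `to_value_grid()` returns the bare value array (a lossless copy);
#' `from_value_grid()` rebuilds a `grid_image` from an array plus explicitly
#' supplied metadata.  Omitted metadata defaults to origin 0, spacing 1 and
#' identity direction.
#'
#' @param img A `grid_image`.
#' @return `to_value_grid()`: a numeric array.
#' @export
to_value_grid <- function(img) img$values

#' @rdname to_value_grid
#' @param grid Numeric array.
#' @inheritParams grid_image
#' @return `from_value_grid()`: a `grid_image`.
#' @export
from_value_grid <- function(grid, origin = NULL, spacing = NULL,
                            direction = NULL, pixel_kind = "float64") {
  grid_image(grid, origin = origin, spacing = spacing, direction = direction,
             pixel_kind = pixel_kind)
}

#' @export
as.array.grid_image <- function(x, ...) x$values

#' Physical center and corners of an image's extent
#'
#' The extent spans half a voxel beyond the first/last voxel centers, so the
#' center sits at continuous index `(size - 1) / 2` and the 2^d corners at
#' continuous indexes -1/2 and size - 1/2 per axis.
#'
#' @param img A `grid_image`.
#' @return `physical_center()`: d-vector (mm); `physical_corners()`: a
#'   2^d x d matrix of corner points (mm).
#' @export
physical_center <- function(img) {
  index_to_physical(img, (image_size(img) - 1) / 2)
}

#' @rdname physical_center
#' @export
physical_corners <- function(img) {
  sz <- image_size(img)
  lims <- lapply(seq_along(sz), function(k) c(-0.5, sz[k] - 0.5))
  idx <- as.matrix(expand.grid(lims))
  colnames(idx) <- NULL
  index_to_physical(img, idx)
}
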