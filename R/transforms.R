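#' Spatial transforms
#'
#' The transform hierarchy mirrors the toolkit family it models:
#'
#' * **Matrix-offset transforms** map `T(x) = A (x - c) + t + c`, where `A`
#'   is a d x d matrix, `c` the fixed center and `t` the translation.  All
#'   global transforms except pure translation are *centered*: rotation and
#'   scaling act about `c`, not the coordinate origin, and moving the center
#'   under a non-identity `A` changes the induced translation.  The derived
#'   offset is `t + c - A c`.  Flavors and their parameter vectors:
#'   `translation` (t), `rigid` 2-D (theta, tx, ty), `rigid` 3-D ZYX Euler
#'   angles in radians (thetaz, thetay, thetax, tx, ty, tz), `similarity`
#'   2-D (s, theta, tx, ty), `similarity` 3-D (s, thetaz, thetay, thetax,
#'   tx, ty, tz), `affine` (row-major A, then t).
#' * **Displacement-field transforms** map `T(x) = x + D(x)` for `x` inside
#'   the field image's physical extent (the field is interpolated
#'   d-linearly, zero-padded past the outermost voxel centers) and act as
#'   the identity outside that bounded domain.
#' * **Composite transforms** hold an ordered stack with stack semantics:
#'   *first added, last applied*.  Adding `T_a` then `T_b` represents
#'   `T_a(T_b(x))`.  Only the last-added member's parameters are exposed for
#'   optimization.
#'
#' @name spatial-transforms
NULL

new_matrix_offset <- function(flavor, d, parameters, center) {
  At <- matrix_from_params(flavor, d, parameters)
  structure(
    list(flavor = flavor, dimension = d, parameters = as.numeric(parameters),
         center = as.numeric(center), A = At$A, t = At$t),
    class = c("matrix_offset_transform", "spatial_transform")
  )
}

param_length <- function(flavor, d) {
  switch(flavor,
    translation = d,
    rigid = if (d == 2L) 3L else 6L,
    similarity = if (d == 2L) 4L else 7L,
    affine = d * d + d,
    pg_stop("FormatError", sprintf("unknown transform flavor '%s'", flavor))
  )
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

rot3_zyx <- function(tz, ty, tx) {
  Rz <- diag(3); Rz[1:2, 1:2] <- rot2(tz)
  Ry <- matrix(c(cos(ty), 0, -sin(ty), 0, 1, 0, sin(ty), 0, cos(ty)), 3L, 3L)
  Rx <- diag(3); Rx[2:3, 2:3] <- rot2(tx)
  Rz %*% Ry %*% Rx
}

matrix_from_params <- function(flavor, d, p) {
  if (length(p) != param_length(flavor, d)) {
    pg_stop("ParameterError", sprintf(
      "flavor '%s' in %d-D expects %d parameters, got %d",
      flavor, d, param_length(flavor, d), length(p)))
  }
  switch(flavor,
    translation = list(A = diag(d), t = as.numeric(p)),
    rigid = if (d == 2L) list(A = rot2(p[1]), t = p[2:3])
            else list(A = rot3_zyx(p[1], p[2], p[3]), t = p[4:6]),
    similarity = if (d == 2L) list(A = p[1] * rot2(p[2]), t = p[3:4])
                 else list(A = p[1] * rot3_zyx(p[2], p[3], p[4]), t = p[5:7]),
    affine = list(A = matrix(p[seq_len(d * d)], d, d, byrow = TRUE),
                  t = p[d * d + seq_len(d)])
  )
}

params_from_matrix <- function(flavor, d, A, t) {
  switch(flavor,
    translation = as.numeric(t),
    rigid = if (d == 2L) c(atan2(A[2, 1], A[1, 1]), t)
            else c(atan2(A[2, 1], A[1, 1]), asin(-A[3, 1]),
                   atan2(A[3, 2], A[3, 3]), t),
    similarity = {
      s <- det(A)^(1 / d)
      R <- A / s
      if (d == 2L) c(s, atan2(R[2, 1], R[1, 1]), t)
      else c(s, atan2(R[2, 1], R[1, 1]), asin(-R[3, 1]),
             atan2(R[3, 2], R[3, 3]), t)
    },
    affine = c(as.numeric(t(A)), as.numeric(t))
  )
}

#' Construct matrix-offset transforms
#'
#' Convenience constructors for the centered matrix-offset family (see
#' [spatial-transforms]).  `identity_transform()` is a d-D translation by
#' zero.
#'
#' @param offset,translation Numeric d-vector, mm.
#' @param d Dimension (2 or 3).
#' @param angle For 2-D: rotation angle, radians.  For 3-D: length-3 vector
#'   of ZYX Euler angles (thetaz, thetay, thetax), radians.
#' @param scale Isotropic scale factor (similarity only).
#' @param center Fixed center `c`, mm.  Defaults to the origin.
#' @param A d x d matrix (affine only).
#' @return A `matrix_offset_transform`.
#' @examples
#' t2 <- rigid_transform(angle = pi / 2, translation = c(0, 0), center = c(1, 1))
#' apply_transform(t2, c(1, 0))
#' @export
translation_transform <- function(offset) {
  new_matrix_offset("translation", length(offset), as.numeric(offset),
                    rep(0, length(offset)))
}

#' @rdname translation_transform
#' @export
identity_transform <- function(d = 3L) translation_transform(rep(0, d))

#' @rdname translation_transform
#' @export
rigid_transform <- function(angle = NULL, translation = NULL, center = NULL,
                            d = if (length(angle) == 1L) 2L else 3L) {
  angle <- angle %||% rep(0, if (d == 2L) 1L else 3L)
  translation <- translation %||% rep(0, d)
  center <- center %||% rep(0, d)
  new_matrix_offset("rigid", d, c(angle, translation), center)
}

#' @rdname translation_transform
#' @export
similarity_transform <- function(scale = 1, angle = NULL, translation = NULL,
                                 center = NULL, d = 2L) {
  angle <- angle %||% rep(0, if (d == 2L) 1L else 3L)
  d <- if (length(angle) == 1L) 2L else 3L
  translation <- translation %||% rep(0, d)
  center <- center %||% rep(0, d)
  new_matrix_offset("similarity", d, c(scale, angle, translation), center)
}

#' @rdname translation_transform
#' @export
affine_transform <- function(A, translation = NULL, center = NULL) {
  A <- as.matrix(A)
  d <- nrow(A)
  translation <- translation %||% rep(0, d)
  center <- center %||% rep(0, d)
  new_matrix_offset("affine", d, c(as.numeric(t(A)), translation), center)
}

#' Displacement-field transform over a bounded domain
#'
#' @param field Numeric array of dimension `c(size, d)`: the last axis holds
#'   the d displacement components (mm) on the field grid.
#' @param origin,spacing,direction Field-grid metadata (as in
#'   [grid_image()]).
#' @return A `displacement_field_transform`.
#' @export
displacement_field_transform <- function(field, origin = NULL, spacing = NULL,
                                         direction = NULL) {
  dims <- dim(field)
  d <- length(dims) - 1L
  if (!d %in% c(2L, 3L) || dims[length(dims)] != d) {
    pg_stop("ShapeError",
            "field must have dimension c(size, d) with d matching its last axis")
  }
  grid <- grid_image(array(0, dims[seq_len(d)]), origin = origin,
                     spacing = spacing, direction = direction)
  structure(
    list(flavor = "displacement_field", dimension = d,
         field = field, grid = grid),
    class = c("displacement_field_transform", "spatial_transform")
  )
}

#' Uniform displacement field covering a physical box
#'
#' Builds a [displacement_field_transform()] whose every voxel carries the
#' same displacement, covering the axis-aligned box `[lower, upper]` with
#' the given grid spacing.
#'
#' @param displacement d-vector, mm.
#' @param lower,upper Physical box corners, mm.
#' @param spacing Field grid spacing, mm (scalar or d-vector).
#' @return A `displacement_field_transform`.
#' @export
uniform_displacement_field <- function(displacement, lower, upper, spacing = 1) {
  d <- length(displacement)
  spacing <- rep(as.numeric(spacing), length.out = d)
  n <- pmax(2L, as.integer(round((upper - lower) / spacing)) + 1L)
  field <- array(0, c(n, d))
  for (k in seq_len(d)) {
    idx <- c(lapply(n, seq_len), list(k))
    field <- do.call(`[<-`, c(list(field), idx, list(value = displacement[k])))
  }
  displacement_field_transform(field, origin = lower, spacing = spacing)
}

#' Composite transform with stack semantics
#'
#' Members are applied *first added, last applied*: `composite_transform(A,
#' B)` maps `x` to `A(B(x))`.  Parameter access ([get_parameters()],
#' [set_parameters()]) delegates to the last-added member only, matching the
#' registration framework's behaviour.
#'
#' @param ... Spatial transforms, in add order.
#' @return A `composite_transform`.
#' @export
composite_transform <- function(...) {
  stack <- list(...)
  if (length(stack) == 1L && is.list(stack[[1]]) &&
      !inherits(stack[[1]], "spatial_transform")) {
    stack <- stack[[1]]
  }
  if (!length(stack) || !all(vapply(stack, inherits, TRUE, "spatial_transform"))) {
    pg_stop("ParameterError", "composite_transform takes one or more spatial transforms")
  }
  d <- stack[[1]]$dimension
  structure(list(flavor = "composite", dimension = d, stack = stack),
            class = c("composite_transform", "spatial_transform"))
}

#' Apply a spatial transform to physical points
#'
#' @param transform A spatial transform.
#' @param x Numeric d-vector or n x d matrix of physical points (mm).
#' @return Mapped point(s), same shape as `x`.
#' @export
apply_transform <- function(transform, x) UseMethod("apply_transform")

#' @export
apply_transform.matrix_offset_transform <- function(transform, x) {
  A <- transform$A
  off <- transform_offset(transform)
  if (is.matrix(x)) {
    sweep(x %*% t(A), 2L, off, `+`)
  } else {
    as.numeric(A %*% as.numeric(x) + off)
  }
}

#' @export
apply_transform.displacement_field_transform <- function(transform, x) {
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  idx <- physical_to_index(transform$grid, xm)
  sz <- image_size(transform$grid)
  inside <- rep(TRUE, nrow(xm))
  for (k in seq_along(sz)) {
    inside <- inside & idx[, k] >= -0.5 & idx[, k] <= sz[k] - 0.5
  }
  out <- xm
  if (any(inside)) {
    d <- transform$dimension
    sub <- idx[inside, , drop = FALSE]
    for (k in seq_len(d)) {
      comp <- component_slice(transform$field, k)
      out[inside, k] <- out[inside, k] +
        interp_array_linear(comp, sub, pad_zero = TRUE)
    }
  }
  if (is.matrix(x)) out else as.numeric(out[1L, ])
}

component_slice <- function(field, k) {
  dims <- dim(field)
  d <- length(dims) - 1L
  idx <- c(lapply(dims[seq_len(d)], seq_len), list(k))
  array(do.call(`[`, c(list(field), idx)), dims[seq_len(d)])
}

#' @export
apply_transform.composite_transform <- function(transform, x) {
  for (j in rev(seq_along(transform$stack))) {
    x <- apply_transform(transform$stack[[j]], x)
  }
  x
}

#' Derived offset of a matrix-offset transform
#'
#' `offset = t + c - A c`, the translation of the equivalent origin-centered
#' map.
#'
#' @param transform A `matrix_offset_transform`.
#' @return Numeric d-vector (mm).
#' @export
transform_offset <- function(transform) {
  as.numeric(transform$t + transform$center -
             transform$A %*% transform$center)
}

#' Invert a matrix-offset transform
#'
#' The inverse keeps the center: `T^-1(y) = A^-1 (y - c) - A^-1 t + c`.
#' Composite and displacement-field transforms are not analytically
#' invertible here and raise `UnsupportedError`.
#'
#' @param transform A spatial transform.
#' @return The inverse `matrix_offset_transform`.
#' @export
invert_transform <- function(transform) UseMethod("invert_transform")

#' @export
invert_transform.matrix_offset_transform <- function(transform) {
  A <- transform$A
  if (abs(det(A)) < 1e-12) {
    pg_stop("NotInvertibleError", "transform matrix is singular")
  }
  Ainv <- solve(A)
  tinv <- as.numeric(-Ainv %*% transform$t)
  flavor <- transform$flavor
  p <- params_from_matrix(flavor, transform$dimension, Ainv, tinv)
  out <- new_matrix_offset(flavor, transform$dimension, p, transform$center)
  # Euler extraction can lose precision near gimbal lock; fall back to affine
  if (max(abs(out$A - Ainv)) > 1e-9 || max(abs(out$t - tinv)) > 1e-9) {
    p <- params_from_matrix("affine", transform$dimension, Ainv, tinv)
    out <- new_matrix_offset("affine", transform$dimension, p, transform$center)
  }
  out
}

#' @export
invert_transform.spatial_transform <- function(transform) {
  pg_stop("UnsupportedError",
          sprintf("inversion is not supported for %s transforms", transform$flavor))
}

#' Get or set a transform's optimizable parameters
#'
#' For matrix-offset transforms this is the flavor-specific flat vector (see
#' [spatial-transforms]); for composites it is the parameter vector of the
#' last-added member only.
#'
#' @param transform A spatial transform.
#' @return `get_parameters()`: numeric vector.
#' @export
get_parameters <- function(transform) UseMethod("get_parameters")

#' @export
get_parameters.matrix_offset_transform <- function(transform) transform$parameters

#' @export
get_parameters.composite_transform <- function(transform) {
  get_parameters(transform$stack[[length(transform$stack)]])
}

#' @export
get_parameters.spatial_transform <- function(transform) {
  pg_stop("UnsupportedError",
          sprintf("parameters not exposed for %s transforms", transform$flavor))
}

#' @rdname get_parameters
#' @param value Numeric parameter vector of the flavor-specific length.
#' @return `set_parameters()`: the modified transform.
#' @export
set_parameters <- function(transform, value) UseMethod("set_parameters")

#' @export
set_parameters.matrix_offset_transform <- function(transform, value) {
  new_matrix_offset(transform$flavor, transform$dimension, value,
                    transform$center)
}

#' @export
set_parameters.composite_transform <- function(transform, value) {
  n <- length(transform$stack)
  transform$stack[[n]] <- set_parameters(transform$stack[[n]], value)
  transform
}

#' @export
print.matrix_offset_transform <- function(x, ...) {
  cat(sprintf("%s transform (%d-D)\n", x$flavor, x$dimension))
  cat("  parameters:", paste(signif(x$parameters, 6), collapse = ", "), "\n")
  cat("  center    :", paste(signif(x$center, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.composite_transform <- function(x, ...) {
  cat(sprintf("composite transform (%d-D), %d members (first added last applied):\n",
              x$dimension, length(x$stack)))
  for (m in x$stack) cat("  -", m$flavor, "\n")
  invisible(x)
}

#' @export
print.displacement_field_transform <- function(x, ...) {
  cat(sprintf("displacement field transform (%d-D), grid %s\n",
              x$dimension, paste(image_size(x$grid), collapse = " x ")))
  invisible(x)
}
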