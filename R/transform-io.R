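#' Read and write transforms as JSON
#'
#' Transforms serialize to a small JSON dialect:
#'
#' ```
#' {"flavor": "rigid", "dimension": 2,
#'  "fixed": {"center": [0, 0]}, "parameters": [0.1, 3, -2]}
#' ```
#'
#' Composites store their members in add order under `"stack"`; a
#' displacement field stores its vector grid inline (`"data"` is base64 of
#' the raw little-endian float64 array in column-major order) together with
#' the full grid metadata.  `read_transform()` of a written file reproduces
#' the original transform's point mapping.
#'
#' @param transform A spatial transform.
#' @param path File path.
#' @return `read_transform()`: the reconstructed transform.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_list <- function(transform) {
  if (inherits(transform, "composite_transform")) {
    list(flavor = "composite", dimension = transform$dimension,
         stack = lapply(transform$stack, transform_to_list))
  } else if (inherits(transform, "displacement_field_transform")) {
    g <- transform$grid
    list(flavor = "displacement_field", dimension = transform$dimension,
         field = list(
           size = as.integer(image_size(g)),
           origin = g$origin, spacing = g$spacing,
           direction = as.numeric(g$direction),  # column-major
           data = jsonlite::base64_enc(
             writeBin(as.numeric(transform$field), raw(), size = 8L,
                      endian = "little"))))
  } else {
    list(flavor = transform$flavor, dimension = transform$dimension,
         fixed = list(center = transform$center),
         parameters = transform$parameters)
  }
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) pg_stop("FormatError", sprintf(
      "cannot parse transform file '%s': %s", path, conditionMessage(e))))
  transform_from_list(obj, path)
}

transform_from_list <- function(obj, path = "<list>") {
  flavor <- obj$flavor
  if (is.null(flavor)) {
    pg_stop("FormatError", sprintf("transform file '%s' lacks a flavor tag", path))
  }
  if (identical(flavor, "composite")) {
    members <- obj$stack
    if (is.null(members) || !length(members)) {
      pg_stop("FormatError", sprintf("composite in '%s' has an empty stack", path))
    }
    return(composite_transform(lapply(members, transform_from_list, path = path)))
  }
  if (identical(flavor, "displacement_field")) {
    f <- obj$field
    sz <- as.integer(unlist(f$size))
    d <- length(sz)
    raw_bytes <- jsonlite::base64_dec(f$data)
    vals <- readBin(raw_bytes, "double", n = length(raw_bytes) %/% 8L,
                    size = 8L, endian = "little")
    if (length(vals) != prod(sz) * d) {
      pg_stop("FormatError", sprintf(
        "displacement field data in '%s' has %d values, expected %d",
        path, length(vals), prod(sz) * d))
    }
    dir <- f$direction
    dir <- if (is.null(dir)) diag(d) else matrix(unlist(dir), d, d)
    return(displacement_field_transform(
      array(vals, c(sz, d)), origin = as.numeric(unlist(f$origin)),
      spacing = as.numeric(unlist(f$spacing)), direction = dir))
  }
  if (!flavor %in% c("translation", "rigid", "similarity", "affine")) {
    pg_stop("FormatError", sprintf(
      "unknown transform flavor '%s' in '%s'", flavor, path))
  }
  d <- as.integer(obj$dimension)
  p <- as.numeric(unlist(obj$parameters))
  ctr <- obj$fixed$center
  ctr <- if (is.null(ctr)) rep(0, d) else as.numeric(unlist(ctr))
  if (length(p) != param_length(flavor, d)) {
    pg_stop("FormatError", sprintf(
      "flavor '%s' in '%s': %d parameters, expected %d",
      flavor, path, length(p), param_length(flavor, d)))
  }
  new_matrix_offset(flavor, d, p, ctr)
}
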