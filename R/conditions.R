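#' Typed error conditions
#'
#' All errors signalled by physgrid carry a specific condition class so
#' callers can distinguish, e.g., a physical-space mismatch from a file-format
#' problem.  The classes used are:
#'
#' * `SpatialMismatchError` — operands do not occupy the same physical space.
#' * `BoundsError` — a region or index lies outside the image grid.
#' * `ShapeError` — value grid and metadata disagree on shape.
#' * `NotInvertibleError` — transform matrix is singular.
#' * `UnsupportedError` — operation undefined for this transform type.
#' * `ParameterError` — parameter vector has the wrong length.
#' * `FormatError` — malformed file or unknown format.
#' * `CorruptFileError` — header and data disagree (e.g. truncated raw file).
#' * `ConfigError` — invalid environment/configuration value.
#' * `IntegrityError` — checksum verification failed.
#' * `UnavailableError` — requested data cannot be obtained.
#' * `KeyLookupError` — name not present in a manifest.
#' * `DegenerateInputError` — empty/full mask or similar degenerate input.
#' * `UndefinedMeasureError` — measure undefined (e.g. both masks empty).
#' * `ConstantImageError` — operation needs intensity variation.
#' * `EmptyResultError` — a detector found nothing.
#' * `SingularFitError` — least-squares problem is rank deficient.
#' * `DisjointDomainError` — no metric samples map into the moving image.
#' * `PixelKindError` — pixel kind unsuitable (cast first).
#'
#' Every condition also carries the class `physgrid_error`.
#'
#' @param class Character scalar, one of the classes above.
#' @param message Human-readable message.
#' @param ... Additional fields stored on the condition object.
#' @return Never returns; signals the condition.
#' @keywords internal
pg_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "physgrid_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
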