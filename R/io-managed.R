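#' Resource-controlled image reading
#'
#' Drop-in replacement for [read_image()] whose behaviour is governed by
#' the `PHYSGRID_SHRINK` environment variable, so switching between
#' full-resolution and sub-sampled data never requires code changes
#' (the decorator pattern).  When the variable is unset, empty or `"1"`,
#' this is exactly `read_image()`.  When it holds an integer factor `k`,
#' the image is read and then resampled to spacing `k * spacing` with
#' `round(size / k)` voxels per axis, preserving origin, direction and the
#' physical extent to within one coarse voxel.
#'
#' @param path Image file path.
#' @param interpolator Interpolator used when resampling (default linear).
#' @return A `grid_image`.
#' @export
read_image_managed <- function(path, interpolator = "linear") {
  img <- read_image(path)
  raw_val <- Sys.getenv("PHYSGRID_SHRINK", unset = "")
  if (raw_val == "" || raw_val == "1") return(img)
  k <- suppressWarnings(as.numeric(raw_val))
  if (is.na(k) || k != round(k) || k < 1) {
    pg_stop("ConfigError", sprintf(
      "PHYSGRID_SHRINK must be a positive integer, got '%s'", raw_val))
  }
  resample_to_spacing(img, img$spacing * k, interpolator = interpolator)
}
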