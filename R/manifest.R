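#' MD5-verified manifest-based data fetching
#'
#' A data manifest is a JSON array of entries
#' `{"filename": ..., "md5": ..., "url": ...}` (`url` optional): the only
#' piece of information collaborators need to share.  `fetch_data()`
#' resolves a filename against a local cache directory: a cached file with
#' a matching MD5 digest is returned without any network activity; an
#' absent or tampered file is (re-)downloaded from the entry's URL, after
#' which the digest is recomputed and compared — on mismatch the download
#' is deleted and an `IntegrityError` raised.  Entries without a URL that
#' are not validly cached raise `UnavailableError`.
#'
#' @param filename Name as listed in the manifest.
#' @param manifest_path Path to the manifest JSON document.
#' @param cache_dir Local cache directory (created if missing); files are
#'   stored flat under their manifest names.
#' @param downloader Transport function `function(url, destfile)`; the
#'   default wraps [utils::download.file()].  Inject a stub for offline
#'   tests.
#' @return Path to the verified local file.
#' @export
fetch_data <- function(filename, manifest_path, cache_dir,
                       downloader = default_downloader) {
  manifest <- read_manifest(manifest_path)
  hit <- which(vapply(manifest, function(e) identical(e$filename, filename), TRUE))
  if (!length(hit)) {
    pg_stop("KeyLookupError",
            sprintf("'%s' is not listed in manifest '%s'", filename, manifest_path))
  }
  entry <- manifest[[hit[1L]]]
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  dest <- file.path(cache_dir, filename)
  if (file.exists(dest) && identical(file_md5(dest), entry$md5)) {
    return(dest)
  }
  if (is.null(entry$url)) {
    pg_stop("UnavailableError", sprintf(
      "'%s' is not validly cached and its manifest entry has no URL", filename))
  }
  downloader(entry$url, dest)
  digest <- file_md5(dest)
  if (!identical(digest, entry$md5)) {
    unlink(dest)
    pg_stop("IntegrityError", sprintf(
      "MD5 mismatch for '%s': manifest %s, downloaded %s (file deleted)",
      filename, entry$md5, digest))
  }
  dest
}

default_downloader <- function(url, destfile) {
  status <- utils::download.file(url, destfile, mode = "wb", quiet = TRUE)
  if (status != 0L) {
    pg_stop("UnavailableError", sprintf("download of '%s' failed", url))
  }
  invisible(destfile)
}

file_md5 <- function(path) unname(tools::md5sum(path))

#' @rdname fetch_data
#' @return `read_manifest()`: list of validated manifest entries.
#' @export
read_manifest <- function(manifest_path) {
  entries <- tryCatch(
    jsonlite::read_json(manifest_path, simplifyVector = FALSE),
    error = function(e) pg_stop("FormatError", sprintf(
      "cannot parse manifest '%s': %s", manifest_path, conditionMessage(e))))
  for (e in entries) {
    if (is.null(e$filename) || is.null(e$md5) ||
        !grepl("^[0-9a-f]{32}$", e$md5)) {
      pg_stop("FormatError", sprintf(
        "manifest '%s': every entry needs a filename and a 32-hex-char md5",
        manifest_path))
    }
  }
  entries
}
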