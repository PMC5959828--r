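# Binary-mask morphology shared by segmentation evaluation and fiducial
# localization: surface extraction, exact Euclidean distance transform with
# anisotropic spacing, and connected components.

as_logical_mask <- function(mask) {
  v <- if (is_grid_image(mask)) mask$values else mask
  bad <- !(v %in% c(0, 1))
  if (any(bad)) {
    pg_stop("ShapeError", "binary label image must contain only 0 and 1")
  }
  array(v > 0.5, dim(v))
}

shift_array <- function(arr, axis, by, fill = FALSE) {
  dims <- dim(arr)
  n <- dims[axis]
  out <- array(fill, dims)
  src <- seq_len(n) - by
  ok <- src >= 1L & src <= n
  if (!any(ok)) return(out)
  ix_out <- lapply(dims, seq_len); ix_out[[axis]] <- which(ok)
  ix_in <- lapply(dims, seq_len); ix_in[[axis]] <- src[ok]
  do.call(`[<-`, c(list(out), ix_out,
                   list(value = do.call(`[`, c(list(arr), ix_in)))))
}

#' Surface voxels of a binary mask
#'
#' A foreground voxel belongs to the surface when at least one face-adjacent
#' neighbour is background or lies outside the image (the image border
#' counts as background).
#'
#' @param mask A binary `grid_image`.
#' @return A binary `grid_image` marking surface voxels.
#' @export
surface_voxels <- function(mask) {
  m <- as_logical_mask(mask)
  d <- length(dim(m))
  has_bg_neighbor <- array(FALSE, dim(m))
  for (axis in seq_len(d)) {
    for (by in c(-1L, 1L)) {
      has_bg_neighbor <- has_bg_neighbor | !shift_array(m, axis, by, fill = FALSE)
    }
  }
  out <- if (is_grid_image(mask)) mask else grid_image(array(0, dim(m)))
  out$values <- array((m & has_bg_neighbor) + 0, dim(m))
  out$pixel_kind <- "label"
  out
}

# Exact 1-D squared-distance transform (lower envelope of parabolas) with
# sample spacing h; f holds squared distances (0 at seeds, Inf elsewhere).
dt1d <- function(f, h) {
  n <- length(f)
  x <- (seq_len(n) - 1) * h
  fin <- which(is.finite(f))
  if (!length(fin)) return(f)
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(fin) > 1L) {
    for (q in fin[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
        if (s <= z[k]) {
          k <- k - 1L
        } else {
          k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
          break
        }
      }
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  out
}

squared_edt <- function(seeds, spacing) {
  dims <- dim(seeds)
  d <- length(dims)
  f <- array(ifelse(seeds, 0, Inf), dims)
  for (axis in seq_len(d)) {
    perm <- c(axis, seq_len(d)[-axis])
    a <- aperm(f, perm)
    m <- matrix(a, nrow = dims[axis])
    for (j in seq_len(ncol(m))) m[, j] <- dt1d(m[, j], spacing[axis])
    f <- aperm(array(m, dim(a)), order(perm))
  }
  f
}

#' Euclidean distance map to a mask's surface
#'
#' Each voxel's value is the physical (mm, anisotropy-aware) Euclidean
#' distance from its center to the nearest surface voxel center of `mask`.
#' The signed variant negates distances inside the mask.  Uses the exact
#' separable lower-envelope distance transform.
#'
#' @param mask A binary `grid_image`, neither empty nor full.
#' @param signed Negative inside the mask?
#' @return A float64 `grid_image` of distances (mm).
#' @export
distance_map <- function(mask, signed = FALSE) {
  m <- as_logical_mask(mask)
  if (!any(m) || all(m)) {
    pg_stop("DegenerateInputError",
            "distance map needs a mask that is neither empty nor full")
  }
  surf <- as_logical_mask(surface_voxels(mask))
  dist <- sqrt(squared_edt(surf, mask$spacing))
  if (signed) dist[m] <- -dist[m]
  out <- mask
  out$values <- dist
  out$pixel_kind <- "float64"
  out
}

#' Connected components / largest component of a binary mask
#'
#' `largest_component()` keeps the connected component with the most
#' voxels; ties break deterministically to the component containing the
#' lexicographically smallest (zero-based) index.
#'
#' @param mask A non-empty binary `grid_image`.
#' @param connectivity `"face"` (4/6-neighbourhood) or `"full"`
#'   (8/26-neighbourhood).
#' @return `label_components()`: an integer array of component labels (0 =
#'   background); `largest_component()`: a binary `grid_image`.
#' @export
largest_component <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  m <- as_logical_mask(mask)
  if (!any(m)) pg_stop("DegenerateInputError", "mask is empty")
  labels <- label_components(m, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # component containing the lexicographically smallest index wins
    cand_lin <- vapply(best, function(lb) {
      idx <- arrayInd(which(labels == lb), dim(m)) - 1L
      ord <- do.call(order, as.data.frame(idx))
      which(labels == lb)[ord[1L]]
    }, 0L)
    first_idx <- arrayInd(cand_lin, dim(m)) - 1L
    ord <- do.call(order, as.data.frame(matrix(first_idx, ncol = length(dim(m)))))
    best <- best[ord[1L]]
  }
  out <- if (is_grid_image(mask)) mask else grid_image(array(0, dim(m)))
  out$values <- array((labels == best) + 0, dim(m))
  out$pixel_kind <- "label"
  out
}

#' @rdname largest_component
#' @param m Logical array.
#' @export
label_components <- function(m, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  dims <- dim(m)
  d <- length(dims)
  offsets <- neighbor_offsets(d, connectivity)
  strides <- cumprod(c(1, dims[-d]))
  labels <- array(0L, dims)
  unvisited <- m
  lab <- 0L
  idx_all <- arrayInd(seq_len(prod(dims)), dims)
  repeat {
    start <- which(unvisited)[1L]
    if (is.na(start)) break
    lab <- lab + 1L
    frontier <- start
    unvisited[start] <- FALSE
    labels[start] <- lab
    while (length(frontier)) {
      fi <- idx_all[frontier, , drop = FALSE]
      nxt <- integer(0)
      for (r in seq_len(nrow(offsets))) {
        ni <- sweep(fi, 2L, offsets[r, ], `+`)
        ok <- rep(TRUE, nrow(ni))
        for (k in seq_len(d)) ok <- ok & ni[, k] >= 1L & ni[, k] <= dims[k]
        if (!any(ok)) next
        lin <- as.integer(1 + (ni[ok, , drop = FALSE] - 1) %*% strides)
        lin <- lin[unvisited[lin]]
        if (length(lin)) {
          unvisited[lin] <- FALSE
          labels[lin] <- lab
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

neighbor_offsets <- function(d, connectivity) {
  if (connectivity == "face") {
    off <- matrix(0L, 2L * d, d)
    for (k in seq_len(d)) {
      off[2L * k - 1L, k] <- -1L
      off[2L * k, k] <- 1L
    }
    off
  } else {
    g <- as.matrix(do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), d)))
    colnames(g) <- NULL
    g[rowSums(abs(g)) > 0L, , drop = FALSE]
  }
}
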