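# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops and explicit formulas only.

# origin + direction %*% (spacing * idx), computed element by element
oracle_index_to_physical <- function(origin, spacing, direction, idx) {
  d <- length(origin)
  p <- numeric(d)
  for (r in seq_len(d)) {
    acc <- 0
    for (c in seq_len(d)) acc <- acc + direction[r, c] * spacing[c] * idx[c]
    p[r] <- origin[r] + acc
  }
  p
}

# nested application of matrix-offset transforms, first in the list applied
# last, each evaluated directly as A (x - c) + t + c
oracle_nested_apply <- function(transforms, x) {
  for (tr in rev(transforms)) {
    x <- as.numeric(tr$A %*% (x - tr$center)) + tr$t + tr$center
  }
  x
}

# brute-force distance (mm) from every voxel center to the nearest surface
# voxel center; surface = foreground voxel with a face-adjacent background
# or out-of-bounds neighbour
oracle_surface_distance <- function(mask_arr, spacing) {
  dims <- dim(mask_arr)
  d <- length(dims)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  fg <- mask_arr > 0.5
  is_surf <- logical(prod(dims))
  for (v in which(fg)) {
    iv <- idx[v, ]
    for (ax in seq_len(d)) {
      for (dlt in c(-1L, 1L)) {
        nb <- iv; nb[ax] <- nb[ax] + dlt
        if (nb[ax] < 1L || nb[ax] > dims[ax]) { is_surf[v] <- TRUE; break }
        if (!fg[matrix(nb, 1L)]) { is_surf[v] <- TRUE; break }
      }
      if (is_surf[v]) break
    }
  }
  surf_xyz <- sweep(idx[is_surf, , drop = FALSE] - 1L, 2L, spacing, `*`)
  all_xyz <- sweep(idx - 1L, 2L, spacing, `*`)
  apply(all_xyz, 1L, function(p) {
    sqrt(min(colSums((t(surf_xyz) - p)^2)))
  })
}

# exhaustive search over all histogram cuts for the Otsu criterion;
# threshold reported as the upper edge of the winning bin
oracle_otsu <- function(x, n_bins) {
  r <- range(x)
  w <- (r[2] - r[1]) / n_bins
  cnt <- tabulate(pmin(pmax(ceiling((x - r[1]) / w), 1L), n_bins), n_bins)
  mids <- r[1] + (seq_len(n_bins) - 0.5) * w
  n <- sum(cnt)
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(cnt[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / n0
    mu1 <- sum(cnt[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  r[1] + best_k * w
}

# hard-binned entropy of a sample, same binning convention as the MI metric
oracle_binned_entropy <- function(x, n_bins) {
  r <- range(x)
  b <- pmin(pmax(ceiling((x - r[1]) / (r[2] - r[1]) * n_bins), 1L), n_bins)
  p <- tabulate(b, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

random_rigid3 <- function() {
  rigid_transform(angle = stats::runif(3, -0.5, 0.5),
                  translation = stats::runif(3, -5, 5),
                  center = stats::runif(3, -10, 10))
}

random_orthonormal <- function(d) {
  qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
}

small_mask <- function(sz, p = 0.3, spacing = rep(1, length(sz))) {
  m <- array(as.numeric(stats::runif(prod(sz)) < p), sz)
  grid_image(m, spacing = spacing, pixel_kind = "label")
}

# rotation angle (rad) and center displacement (mm) of est composed with
# truth; both are ~0 when est inverts truth exactly
recovery_error <- function(est, truth, center) {
  comp_A <- est$A %*% truth$A
  d <- nrow(comp_A)
  rot <- if (d == 3L) acos(min(1, max(-1, (sum(diag(comp_A)) - 1) / 2)))
         else acos(min(1, max(-1, comp_A[1, 1])))
  trans <- sqrt(sum((apply_transform(est, apply_transform(truth, center)) - center)^2))
  c(rot = rot, trans = trans)
}
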