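#' Reference segmentation by majority vote
#'
#' A voxel is foreground when *strictly more than half* of the raters mark
#' it; with an even rater count, exact ties go to background.  All rater
#' masks must occupy the same physical space.
#'
#' @param raters Non-empty list of binary `grid_image`s on one grid.
#' @return A binary `grid_image`.
#' @export
majority_vote <- function(raters) {
  check_rater_stack(raters, min_raters = 1L)
  votes <- Reduce(`+`, lapply(raters, function(r) as_logical_mask(r) + 0))
  out <- raters[[1L]]
  out$values <- array((votes > length(raters) / 2) + 0, dim(votes))
  out$pixel_kind <- "label"
  out
}

check_rater_stack <- function(raters, min_raters) {
  if (length(raters) < min_raters) {
    pg_stop("ParameterError",
            sprintf("need at least %d rater segmentation(s)", min_raters))
  }
  for (r in raters[-1L]) {
    if (!same_physical_space(raters[[1L]], r)) {
      pg_stop("SpatialMismatchError",
              "rater segmentations do not occupy the same physical space")
    }
  }
  invisible(TRUE)
}

#' STAPLE: simultaneous truth and performance level estimation
#'
#' Expectation-maximization estimate of a consensus segmentation together
#' with each rater's sensitivity `p` (true-positive rate) and specificity
#' `q` (true-negative rate).  With rater decisions `D_ij` at voxel `i`, the
#' E-step computes the foreground posterior
#' `W_i = a_i / (a_i + b_i)` where
#' `a_i = gamma * prod_j p_j^D_ij (1 - p_j)^(1 - D_ij)` and
#' `b_i = (1 - gamma) * prod_j (1 - q_j)^D_ij q_j^(1 - D_ij)`;
#' the M-step re-estimates
#' `p_j = sum_i W_i D_ij / sum_i W_i` and
#' `q_j = sum_i (1 - W_i)(1 - D_ij) / sum_i (1 - W_i)`.
#' Iteration stops when the largest posterior change falls below `tol` or
#' after `max_iter` iterations.  Raters start at `p = q = 0.99` (avoiding
#' the absorbing perfect-rater state) and the foreground prior `gamma`
#' defaults to the mean foreground fraction across raters.
#'
#' @param raters List of >= 2 binary `grid_image`s on one grid.
#' @param prior Foreground prior `gamma` in (0, 1), or `"auto"`.
#' @param tol Convergence threshold on `max |delta W|`.
#' @param max_iter Maximum EM iterations.
#' @return A `staple_result`: list with `weight_map` (posterior
#'   `grid_image` in `[0, 1]`), `consensus` (binary `grid_image`, `W >=
#'   0.5`), `p`, `q` (per-rater vectors), `prior`, `iterations`,
#'   `converged`.
#' @references Warfield, Zou & Wells (2004), IEEE TMI 23(7):903-921.
#' @export
staple <- function(raters, prior = "auto", tol = 1e-7, max_iter = 100L) {
  check_rater_stack(raters, min_raters = 2L)
  D <- vapply(raters, function(r) as.numeric(as_logical_mask(r)),
              numeric(length(raters[[1L]]$values)))
  fg_frac <- colMeans(D)
  if (all(colSums(D) == 0) || all(colSums(1 - D) == 0)) {
    pg_stop("DegenerateInputError",
            "all raters empty or all raters full; STAPLE is undefined")
  }
  gamma <- if (identical(prior, "auto")) mean(fg_frac) else as.numeric(prior)
  if (!(gamma > 0 && gamma < 1)) {
    pg_stop("ParameterError", "prior must lie strictly inside (0, 1)")
  }
  J <- ncol(D)
  p <- rep(0.99, J); q <- rep(0.99, J)
  W <- rep(gamma, nrow(D))
  eps <- 1e-12
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    pc <- pmin(pmax(p, eps), 1 - eps)
    qc <- pmin(pmax(q, eps), 1 - eps)
    log_a <- log(gamma) + D %*% log(pc) + (1 - D) %*% log(1 - pc)
    log_b <- log(1 - gamma) + D %*% log(1 - qc) + (1 - D) %*% log(qc)
    mx <- pmax(log_a, log_b)
    a <- exp(log_a - mx); b <- exp(log_b - mx)
    W_new <- as.numeric(a / (a + b))
    delta <- max(abs(W_new - W))
    W <- W_new
    sw <- sum(W); swc <- sum(1 - W)
    p <- as.numeric(crossprod(D, W)) / sw
    q <- as.numeric(crossprod(1 - D, 1 - W)) / swc
    if (delta < tol) { converged <- TRUE; break }
  }
  wm <- raters[[1L]]
  wm$values <- array(W, dim(raters[[1L]]$values))
  wm$pixel_kind <- "float64"
  cons <- raters[[1L]]
  cons$values <- array((W >= 0.5) + 0, dim(wm$values))
  cons$pixel_kind <- "label"
  structure(list(weight_map = wm, consensus = cons, p = p, q = q,
                 prior = gamma, iterations = iterations,
                 converged = converged),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("staple_result: %d raters, %d iterations (%s)\n",
              length(x$p), x$iterations,
              if (x$converged) "converged" else "max_iter"))
  cat("  sensitivity p:", paste(sprintf("%.4f", x$p), collapse = ", "), "\n")
  cat("  specificity q:", paste(sprintf("%.4f", x$q), collapse = ", "), "\n")
  invisible(x)
}

#' Volumetric overlap measures
#'
#' With evaluated mask `E` and reference mask `R`:
#' Dice `2|E∩R|/(|E|+|R|)`, Jaccard `|E∩R|/|E∪R|`, volume similarity
#' `2(|E|-|R|)/(|E|+|R|)`, false-negative fraction `|R\\E|/|R|` and
#' false-positive fraction `|E\\R|/|E|`.
#'
#' @param evaluated,reference Binary `grid_image`s on the same grid.
#' @return An `overlap_report`: list with fields `dice`, `jaccard`,
#'   `volume_similarity`, `false_negative_fraction`,
#'   `false_positive_fraction`.
#' @export
overlap_measures <- function(evaluated, reference) {
  if (!same_physical_space(evaluated, reference)) {
    pg_stop("SpatialMismatchError",
            "evaluated and reference masks do not share a physical grid")
  }
  e <- as_logical_mask(evaluated); r <- as_logical_mask(reference)
  ne <- sum(e); nr <- sum(r)
  if (ne == 0 && nr == 0) {
    pg_stop("UndefinedMeasureError", "both masks are empty; overlap undefined")
  }
  inter <- sum(e & r); uni <- sum(e | r)
  structure(list(
    dice = 2 * inter / (ne + nr),
    jaccard = inter / uni,
    volume_similarity = 2 * (ne - nr) / (ne + nr),
    false_negative_fraction = if (nr > 0) sum(r & !e) / nr else NA_real_,
    false_positive_fraction = if (ne > 0) sum(e & !r) / ne else NA_real_
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0("overlap_report: dice %.4f, jaccard %.4f, ",
                     "volume similarity %+.4f, fnf %.4f, fpf %.4f\n"),
              x$dice, x$jaccard, x$volume_similarity,
              x$false_negative_fraction, x$false_positive_fraction))
  invisible(x)
}

#' Directed surface-distance measures
#'
#' Statistics (mm) of the reference segmentation's unsigned surface
#' distance map sampled at the evaluated segmentation's surface voxels:
#' the label-mask-over-intensity pattern.  The maximum is the directed
#' (voxelized) Hausdorff distance.  The measure is *directed*: swapping
#' the arguments generally changes the report.
#'
#' @param evaluated,reference Binary `grid_image`s on the same grid,
#'   both non-empty and non-full.
#' @return A `surface_distance_report`: list with `mean`, `median`, `std`,
#'   `max` (all mm), and `n_surface_voxels`.
#' @export
surface_distance_measures <- function(evaluated, reference) {
  if (!same_physical_space(evaluated, reference)) {
    pg_stop("SpatialMismatchError",
            "evaluated and reference masks do not share a physical grid")
  }
  dmap <- distance_map(reference, signed = FALSE)
  surf <- as_logical_mask(surface_voxels(evaluated))
  if (!any(surf)) {
    pg_stop("DegenerateInputError", "evaluated mask has no surface voxels")
  }
  dists <- abs(dmap$values[surf])
  structure(list(mean = mean(dists), median = stats::median(dists),
                 std = stats::sd(dists), max = max(dists),
                 n_surface_voxels = sum(surf)),
            class = "surface_distance_report")
}

#' @export
print.surface_distance_report <- function(x, ...) {
  cat(sprintf(
    "surface_distance_report (mm): mean %.4f, median %.4f, std %.4f, max %.4f (n=%d)\n",
    x$mean, x$median, x$std, x$max, x$n_surface_voxels))
  invisible(x)
}
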