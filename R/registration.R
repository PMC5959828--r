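#' Multi-resolution intensity-based registration
#'
#' The framework follows the virtual-domain three-transform model: a point
#' in the fixed image domain is mapped to the moving image domain as
#'
#' \deqn{{}^m p = T_{opt}(T_m(T_f^{-1}({}^f p)))}
#'
#' where `t_fixed` maps the virtual domain to the fixed domain (never
#' modified), `t_moving` maps it to the moving domain (never modified) and
#' `t_opt`'s parameters are optimized.  By default the virtual and fixed
#' domains coincide (`t_fixed = t_moving = identity`) and the model reduces
#' to the traditional single-transform registration `T_opt(p)`.
#'
#' Optimization is plain gradient descent on the metric with central
#' finite-difference gradients, preconditioned by per-parameter scales
#' derived from physical shift (see [scales_from_physical_shift()]) so that
#' a unit change in an angle (radians) and in a translation (mm) move
#' points by comparable physical distances.  Each pyramid level smooths
#' both images with a Gaussian (sigma in mm), shrinks them by an integer
#' factor, draws a fresh uniform voxel sample of the fixed image, and
#' continues from the previous level's transform.
#'
#' @param fixed,moving `grid_image`s with float pixel kind (use
#'   [cast_image()] first otherwise).
#' @param t_opt_init Initial optimized transform (a
#'   `matrix_offset_transform`), e.g. from
#'   [initialize_geometric_center()].
#' @param metric `"mean_squares"` or `"mutual_information"` (negated MI,
#'   lower is better).
#' @param sampling_fraction Fraction of fixed voxels sampled per level, in
#'   (0, 1].  The drawn count is floored at `min(n_voxels, max(4 * mi_bins,
#'   200))` so coarse levels keep the joint histogram populated.
#' @param mi_bins Number of histogram bins per axis for mutual information.
#' @param learning_rate Positive physical step length in mm, or `"auto"`
#'   (default): each level starts at one voxel of the (level) fixed image.
#'   Every accepted descent step displaces the extent corners by at most
#'   this length; the step halves whenever a trial step fails to decrease
#'   the metric.
#' @param max_iterations Per-level iteration cap.
#' @param convergence_tol Convergence threshold on the windowed mean
#'   absolute metric change.
#' @param convergence_window Number of recent iterations averaged for the
#'   convergence test.
#' @param gradient_delta Central-difference perturbation per *scaled*
#'   parameter unit (approximately mm of corner displacement), or
#'   `"auto"`: 1e-3 for mean squares, 0.25 for sampled mutual information,
#'   whose histogram estimate is only piecewise smooth and needs a
#'   perturbation large enough to average across bin-transition kinks.
#' @param schedule List of `c(shrink_factor, smoothing_sigma_mm)` per
#'   level, coarse to fine.
#' @param seed Integer seed controlling voxel sampling.
#' @param t_fixed,t_moving Optional virtual-domain transforms (defaults:
#'   identity).
#' @return A `registration_problem`.
#' @export
registration_problem <- function(fixed, moving, t_opt_init,
                                 metric = c("mean_squares", "mutual_information"),
                                 sampling_fraction = 0.05,
                                 mi_bins = 50L,
                                 learning_rate = "auto",
                                 max_iterations = 100L,
                                 convergence_tol = 1e-6,
                                 convergence_window = 10L,
                                 gradient_delta = "auto",
                                 schedule = list(c(4, 2), c(2, 1), c(1, 0)),
                                 seed = 1L,
                                 t_fixed = NULL, t_moving = NULL) {
  metric <- match.arg(metric)
  if (!(sampling_fraction > 0 && sampling_fraction <= 1)) {
    pg_stop("ParameterError", "sampling_fraction must be in (0, 1]")
  }
  sched <- lapply(schedule, function(s) c(shrink = s[[1]], sigma = s[[2]]))
  if (any(vapply(sched, `[`, 0, 1L) < 1)) {
    pg_stop("ParameterError", "shrink factors must be >= 1")
  }
  structure(
    list(fixed = fixed, moving = moving, t_opt_init = t_opt_init,
         metric = metric, sampling_fraction = sampling_fraction,
         mi_bins = as.integer(mi_bins), learning_rate = learning_rate,
         max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol,
         convergence_window = as.integer(convergence_window),
         gradient_delta = if (identical(gradient_delta, "auto")) {
           if (metric == "mean_squares") 1e-3 else 0.25
         } else as.numeric(gradient_delta),
         schedule = sched, seed = as.integer(seed),
         t_fixed = t_fixed %||% identity_transform(image_ndim(fixed)),
         t_moving = t_moving %||% identity_transform(image_ndim(moving))),
    class = "registration_problem"
  )
}

#' Map a fixed-domain point into the moving domain
#'
#' Evaluates the three-transform chain `T_opt(T_m(T_f^-1(p)))`.
#'
#' @param prob A `registration_problem`.
#' @param t_opt Current optimized transform.
#' @param p Physical point (d-vector) or n x d matrix.
#' @return Mapped point(s).
#' @export
map_fixed_to_moving <- function(prob, t_opt, p) {
  p <- apply_transform(invert_transform(prob$t_fixed), p)
  p <- apply_transform(prob$t_moving, p)
  apply_transform(t_opt, p)
}

#' Initialize a transform by aligning geometric centers
#'
#' Returns a transform of the requested flavor whose matrix is the
#' identity, whose center is the physical center of the fixed image's
#' extent, and whose translation carries the fixed center onto the moving
#' center.
#'
#' @param fixed,moving `grid_image`s of equal dimension.
#' @param flavor `"translation"`, `"rigid"`, `"similarity"` or `"affine"`.
#' @return A `matrix_offset_transform`.
#' @export
initialize_geometric_center <- function(fixed, moving,
                                        flavor = c("rigid", "translation",
                                                   "similarity", "affine")) {
  flavor <- match.arg(flavor)
  d <- image_ndim(fixed)
  if (d != image_ndim(moving)) {
    pg_stop("ShapeError", "fixed and moving images must share a dimension")
  }
  ctr_f <- physical_center(fixed)
  tr <- physical_center(moving) - ctr_f
  p <- switch(flavor,
    translation = tr,
    rigid = c(rep(0, if (d == 2L) 1L else 3L), tr),
    similarity = c(1, rep(0, if (d == 2L) 1L else 3L), tr),
    affine = c(as.numeric(diag(d)), tr)
  )
  new_matrix_offset(flavor, d, p, ctr_f)
}

# ---- metric machinery ------------------------------------------------------

# Sample values of `img` at physical points; list(values, valid).
sample_image_at_points <- function(img, points, interpolator = "linear") {
  idx <- physical_to_index(img, points)
  sample_at_index(img$values, idx, interpolator)
}

mean_squares_from_samples <- function(fv, mv, valid) {
  if (!any(valid)) {
    pg_stop("DisjointDomainError",
            "no metric samples fall inside the moving image support")
  }
  mean((fv[valid] - mv[valid])^2)
}

# Dense joint histogram with linear (triangular-kernel) binning: each sample
# spreads its mass over the two adjacent bins along each axis, keeping the
# sampled MI continuous in the transform parameters so finite-difference
# gradients are informative.
soft_hist_coords <- function(x, nb, r = range(x)) {
  if (r[2] - r[1] <= 0) {
    pg_stop("ConstantImageError",
            "sampled intensities are constant; mutual information undefined")
  }
  u <- (x - r[1]) / (r[2] - r[1]) * nb - 0.5
  f <- floor(u)
  list(lo = pmin(pmax(f, 0), nb - 1), hi = pmin(pmax(f + 1, 0), nb - 1),
       w = u - f)
}

joint_soft_histogram <- function(x, y, nb, rx = range(x), ry = range(y)) {
  cx <- soft_hist_coords(x, nb, rx)
  cy <- soft_hist_coords(y, nb, ry)
  jt <- numeric(nb * nb)
  add <- function(bi, bj, w) {
    lin <- 1 + bi + nb * bj
    agg <- rowsum(w, lin, reorder = FALSE)
    jt[as.integer(rownames(agg))] <<- jt[as.integer(rownames(agg))] + agg[, 1]
  }
  add(cx$lo, cy$lo, (1 - cx$w) * (1 - cy$w))
  add(cx$hi, cy$lo, cx$w * (1 - cy$w))
  add(cx$lo, cy$hi, (1 - cx$w) * cy$w)
  add(cx$hi, cy$hi, cx$w * cy$w)
  matrix(jt, nb, nb)
}

hard_bin <- function(x, nb, r) {
  if (r[2] - r[1] <= 0) {
    pg_stop("ConstantImageError",
            "sampled intensities are constant; mutual information undefined")
  }
  pmin(pmax(ceiling((x - r[1]) / (r[2] - r[1]) * nb), 1L), nb)
}

joint_hard_histogram <- function(x, y, nb, rx = range(x), ry = range(y)) {
  bx <- hard_bin(x, nb, rx)
  by <- hard_bin(y, nb, ry)
  matrix(tabulate(bx + nb * (by - 1L), nb * nb), nb, nb)
}

mutual_information_from_samples <- function(fv, mv, valid, nb,
                                            rx = NULL, ry = NULL,
                                            soft = FALSE) {
  nvalid <- sum(valid)
  if (nvalid < nb) {
    pg_stop("DisjointDomainError", sprintf(
      "only %d valid metric samples; mutual information needs at least %d",
      nvalid, nb))
  }
  hist_fun <- if (soft) joint_soft_histogram else joint_hard_histogram
  jt <- hist_fun(fv[valid], mv[valid], nb,
                 rx %||% range(fv[valid]),
                 ry %||% range(mv[valid]))
  pj <- jt / sum(jt)
  pf <- rowSums(pj)
  pm <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / (pf[row(pj)[nz]] * pm[col(pj)[nz]])))
  -mi
}

#' Similarity metrics at explicit sample points
#'
#' Evaluate the mean-squares or (negated) mutual-information metric between
#' the problem's fixed and moving images at the given fixed-domain sample
#' points, under the transform chain with the supplied `t_opt`.  Samples
#' whose mapped location falls outside the moving image support are
#' excluded.  Mutual information uses a dense `mi_bins` x `mi_bins`
#' equal-width joint histogram spanning each image's sampled min-max;
#' `0 log 0` terms are dropped, and the value returned is `-MI` so that
#' lower is better for both metrics.  (Internally, [register()] optimizes
#' a linearly-binned surrogate of this quantity — see the package
#' vignette — but the definition here is the plug-in histogram estimator,
#' for which MI of an image with itself equals the sampled entropy.)
#'
#' @param prob A `registration_problem`.
#' @param t_opt Current optimized transform.
#' @param sample_points n x d matrix of fixed-domain physical points.
#' @return Scalar metric value.
#' @export
metric_mean_squares <- function(prob, t_opt, sample_points) {
  fs <- sample_image_at_points(prob$fixed, sample_points)
  ms <- sample_image_at_points(prob$moving,
                               map_fixed_to_moving(prob, t_opt, sample_points))
  mean_squares_from_samples(fs$values, ms$values, fs$valid & ms$valid)
}

#' @rdname metric_mean_squares
#' @export
metric_mutual_information <- function(prob, t_opt, sample_points) {
  fs <- sample_image_at_points(prob$fixed, sample_points)
  ms <- sample_image_at_points(prob$moving,
                               map_fixed_to_moving(prob, t_opt, sample_points))
  mutual_information_from_samples(fs$values, ms$values,
                                  fs$valid & ms$valid, prob$mi_bins)
}

#' Parameter scales from physical shift
#'
#' For each parameter, the scale is the largest physical displacement of
#' any corner of the fixed image's extent per unit parameter change
#' (central difference, delta = 1e-4), floored at 1e-12.  Gradient descent
#' divides gradient component i by `scale[i]^2`, so a unit *scaled* change
#' in every parameter has a similar effect in physical space — essential
#' when the parameter vector mixes radians and millimeters.  Scales depend
#' only on the geometry, never on image intensities.
#'
#' @param prob A `registration_problem` (only its fixed-image geometry is
#'   used).
#' @param t_opt Transform whose parameters are being scaled.
#' @return Numeric vector of per-parameter scales.
#' @export
scales_from_physical_shift <- function(prob, t_opt) {
  corners <- physical_corners(prob$fixed)
  theta <- get_parameters(t_opt)
  delta <- 1e-4
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + delta
    dn <- theta; dn[i] <- dn[i] - delta
    shift <- apply_transform(set_parameters(t_opt, up), corners) -
             apply_transform(set_parameters(t_opt, dn), corners)
    max(sqrt(rowSums(shift^2))) / (2 * delta)
  }, 0) |> pmax(1e-12)
}

# ---- the optimizer ---------------------------------------------------------

#' Run the registration
#'
#' Executes the multi-resolution schedule described in
#' [registration_problem()].  Per level: Gaussian-smooth (sigma in mm) and
#' shrink both images, draw the seeded uniform voxel sample of the fixed
#' image, then run scaled gradient descent on `t_opt`'s parameters until
#' the windowed mean absolute metric change drops below `convergence_tol`,
#' the physical step length decays below 1e-4 of its initial value, or
#' `max_iterations` is reached.  A trial step that would increase the
#' metric is rejected and the step length halved, so the accepted metric
#' sequence never rises.  The transform carries over between levels.
#'
#' @param prob A `registration_problem`.
#' @return A `registration_result`: list with `t_opt_final`,
#'   `metric_trace` (data.frame: level, iteration, metric), `stop_reason`
#'   (`"converged"` or `"max_iterations"`, final level), `final_metric`.
#' @export
register <- function(prob) {
  for (side in c("fixed", "moving")) {
    if (!prob[[side]]$pixel_kind %in% c("float32", "float64")) {
      pg_stop("PixelKindError", sprintf(
        "%s image has pixel kind '%s'; registration requires a floating point type — convert with cast_image()",
        side, prob[[side]]$pixel_kind))
    }
  }
  t_opt <- prob$t_opt_init
  pre_chain_identity <-
    is_zero_translation(prob$t_fixed) && is_zero_translation(prob$t_moving)
  trace_level <- integer(0); trace_iter <- integer(0); trace_val <- numeric(0)
  stop_reason <- "max_iterations"

  for (lev in seq_along(prob$schedule)) {
    shrink <- prob$schedule[[lev]][["shrink"]]
    sigma <- prob$schedule[[lev]][["sigma"]]
    f_lev <- shrink_image(gaussian_smooth(prob$fixed, sigma), shrink)
    m_lev <- shrink_image(gaussian_smooth(prob$moving, sigma), shrink)

    n_vox <- prod(image_size(f_lev))
    n_s <- min(n_vox, max(round(prob$sampling_fraction * n_vox),
                          min(n_vox, max(4L * prob$mi_bins, 200L))))
    lin <- with_local_seed(prob$seed + lev, sample.int(n_vox, n_s))
    idx0 <- arrayInd(lin, image_size(f_lev)) - 1L
    pts <- index_to_physical(f_lev, idx0)
    fv <- f_lev$values[lin]
    p_pre <- if (pre_chain_identity) pts else {
      apply_transform(prob$t_moving,
                      apply_transform(invert_transform(prob$t_fixed), pts))
    }

    # Histogram ranges are frozen per level (fixed: the sample; moving: the
    # whole level image) so the MI metric stays smooth in the parameters.
    eval_metric <- local({
      metric <- prob$metric; nb <- prob$mi_bins
      mvals <- m_lev$values; mimg <- m_lev
      rx <- range(fv); ry <- range(mvals)
      function(tr) {
        midx <- physical_to_index(mimg, apply_transform(tr, p_pre))
        s <- sample_at_index(mvals, midx, "linear")
        if (metric == "mean_squares") {
          mean_squares_from_samples(fv, s$values, s$valid)
        } else {
          mutual_information_from_samples(fv, s$values, s$valid, nb, rx, ry,
                                          soft = TRUE)
        }
      }
    })

    scales <- scales_from_physical_shift(
      list(fixed = f_lev), t_opt)
    theta <- get_parameters(t_opt)
    m_cur <- eval_metric(t_opt)
    # physical step length, mm: "auto" starts each level at one voxel
    step <- if (identical(prob$learning_rate, "auto")) min(f_lev$spacing)
            else prob$learning_rate
    min_step <- 1e-4 * step
    corners <- physical_corners(f_lev)
    recent <- numeric(0)
    stop_reason <- "max_iterations"

    for (it in seq_len(prob$max_iterations)) {
      grad <- vapply(seq_along(theta), function(i) {
        h <- prob$gradient_delta / scales[i]
        up <- theta; up[i] <- up[i] + h
        dn <- theta; dn[i] <- dn[i] - h
        (eval_metric(set_parameters(t_opt, up)) -
         eval_metric(set_parameters(t_opt, dn))) / (2 * h)
      }, 0)
      step_dir <- grad / scales^2
      shift <- apply_transform(set_parameters(t_opt, theta - step_dir), corners) -
               apply_transform(set_parameters(t_opt, theta), corners)
      max_shift <- max(sqrt(rowSums(shift^2)))
      if (max_shift < 1e-14) {
        trace_level <- c(trace_level, lev)
        trace_iter <- c(trace_iter, it)
        trace_val <- c(trace_val, m_cur)
        stop_reason <- "converged"
        break
      }
      # scale the descent direction so the largest induced physical
      # displacement of any extent corner equals the current step length
      theta_new <- theta - (step / max_shift) * step_dir
      m_new <- eval_metric(set_parameters(t_opt, theta_new))
      if (is.finite(m_new) && m_new <= m_cur) {
        theta <- theta_new
        delta_m <- m_cur - m_new
        m_cur <- m_new
      } else {
        step <- step / 2
        delta_m <- 0
      }
      t_opt <- set_parameters(t_opt, theta)
      trace_level <- c(trace_level, lev)
      trace_iter <- c(trace_iter, it)
      trace_val <- c(trace_val, m_cur)
      recent <- c(recent, abs(delta_m))
      if (length(recent) > prob$convergence_window) {
        recent <- recent[-1L]
      }
      if (step < min_step ||
          (length(recent) == prob$convergence_window &&
           mean(recent) < prob$convergence_tol)) {
        stop_reason <- "converged"
        break
      }
    }
  }

  structure(
    list(t_opt_final = t_opt,
         metric_trace = data.frame(level = trace_level,
                                   iteration = trace_iter,
                                   metric = trace_val),
         stop_reason = stop_reason,
         final_metric = trace_val[length(trace_val)]),
    class = "registration_result"
  )
}

is_zero_translation <- function(tr) {
  inherits(tr, "matrix_offset_transform") &&
    tr$flavor == "translation" && all(tr$parameters == 0)
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result\n")
  cat("  final metric:", format(x$final_metric), "\n")
  cat("  stop reason :", x$stop_reason, "\n")
  cat("  iterations  :", nrow(x$metric_trace), "over",
      length(unique(x$metric_trace$level)), "levels\n")
  print(x$t_opt_final)
  invisible(x)
}

#' Write a metric trace as CSV
#'
#' @param result A `registration_result`.
#' @param path Output CSV path (columns: iteration, level, metric).
#' @export
write_metric_trace <- function(result, path) {
  utils::write.csv(
    result$metric_trace[, c("iteration", "level", "metric")],
    path, row.names = FALSE)
  invisible(path)
}
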