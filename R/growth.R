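# Growth module: conditional microtubule growth inside a cell geometry.

#' Growth model parameters
#'
#' Parameters of the centrosome-nucleated growth model.  `n`, `mu_um`
#' and `collinearity` are the free parameters estimated by matching;
#' the remaining fields are model constants: each growth step is
#' 0.2 um (one voxel); boundary rebounds are confined to a local cone
#' of half-angle 63.9 degrees (cosine 0.44); growth terminates when,
#' within a sliding window of 30 steps, more than 3 unordered pairs of
#' step directions differ by more than 120 degrees; a microtubule of a
#' desired length is attempted at most 100 times.
#'
#' @param n Number of microtubules (>= 0).
#' @param mu_um Mean of the length distribution, micrometres (> 0).
#' @param collinearity Cosine of the angle between consecutive steps,
#'   in (0, 1].
#' @param erlang_shape_k Integer shape of the Erlang length
#'   distribution (>= 1, default 2).
#' @param step_um Step length in micrometres (default 0.2).
#' @param cos_alpha_local Cosine of the local rebound half-angle
#'   (default 0.44, i.e. 63.9 degrees).
#' @param alpha_global_deg Global pairwise angle threshold in degrees
#'   (default 120).
#' @param window_steps Sliding-window length in steps (default 30).
#' @param max_bad_pairs Maximum tolerated pairs over the global angle
#'   (default 3).
#' @param max_retries Attempts per desired length before declaring the
#'   parameters ungenerable (default 100).
#' @param n_rebound_candidates Candidate directions sampled in the
#'   local cone when a step is blocked (default 50).
#' @param window_pair_mode Which step-direction pairs the sliding
#'   window counts: `"consecutive"` (default) counts angles between
#'   successive steps, `"all"` counts every unordered pair in the
#'   window.  The all-pairs reading terminates any net direction
#'   reversal completed within the window, which makes filaments much
#'   longer than the cell ungenerable; the consecutive reading keeps
#'   the grid of library parameters generable (see the package
#'   vignette).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(n, mu_um, collinearity, erlang_shape_k = 2L,
                          step_um = 0.2, cos_alpha_local = 0.44,
                          alpha_global_deg = 120, window_steps = 30L,
                          max_bad_pairs = 3L, max_retries = 100L,
                          n_rebound_candidates = 50L,
                          window_pair_mode = c("consecutive", "all")) {
  window_pair_mode <- match.arg(window_pair_mode)
  stopifnot(n >= 0, mu_um > 0, collinearity > 0, collinearity <= 1,
            erlang_shape_k >= 1, step_um > 0, max_retries >= 1)
  structure(list(n = as.integer(n), mu_um = mu_um,
                 collinearity = collinearity,
                 erlang_shape_k = as.integer(erlang_shape_k),
                 step_um = step_um, cos_alpha_local = cos_alpha_local,
                 alpha_global_deg = alpha_global_deg,
                 window_steps = as.integer(window_steps),
                 max_bad_pairs = as.integer(max_bad_pairs),
                 max_retries = as.integer(max_retries),
                 n_rebound_candidates = as.integer(n_rebound_candidates),
                 window_pair_mode = window_pair_mode),
            class = "growth_params")
}

#' Sample microtubule lengths from the Erlang distribution
#'
#' Lengths are Erlang with integer shape `k` and rate `k / mu_um`, so
#' the mean is exactly `mu_um`; each draw is rounded to the nearest
#' positive multiple of the step length so a desired length always
#' corresponds to a whole number of growth steps.
#'
#' @param n Number of draws (>= 0).
#' @param mu_um Mean length in micrometres.
#' @param k Integer Erlang shape (default 2).
#' @param step_um Step length for rounding (default 0.2).
#' @return Numeric vector of `n` lengths, positive multiples of
#'   `step_um`.
#' @export
sample_lengths <- function(n, mu_um, k = 2L, step_um = 0.2) {
  stopifnot(n >= 0, mu_um > 0, k >= 1)
  if (n == 0) return(numeric(0))
  x <- rgamma(n, shape = k, rate = k / mu_um)
  pmax(step_um, round(x / step_um) * step_um)
}

#' Draw the next step direction on the collinearity cone
#'
#' Returns a unit vector whose dot product with `prev_dir` equals
#' `cos_alpha` exactly (the lateral surface of the cone of aperture
#' `2 * acos(cos_alpha)`), with azimuth uniform on `[0, 2 * pi)`.
#'
#' @param prev_dir Unit 3-vector of the previous step.
#' @param cos_alpha Cosine of the cone half-angle, in (0, 1].
#' @return Unit 3-vector.
#' @export
step_direction <- function(prev_dir, cos_alpha) {
  stopifnot(length(prev_dir) == 3L, cos_alpha > 0, cos_alpha <= 1)
  nrm <- sqrt(sum(prev_dir^2))
  if (nrm == 0) stop("prev_dir must be nonzero")
  d <- prev_dir / nrm
  if (cos_alpha == 1) return(d)
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(d, a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(d, e1)
  phi <- runif(1, 0, 2 * pi)
  sin_a <- sqrt(1 - cos_alpha^2)
  v <- cos_alpha * d + sin_a * (cos(phi) * e1 + sin(phi) * e2)
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Sliding-window curvature check
#'
#' Growth continues only while the trailing window of step directions
#' contains at most `max_bad_pairs` unordered pairs whose 3D angle
#' exceeds `alpha_global_deg`.
#'
#' @param step_dirs Matrix (rows = unit direction vectors) of at most
#'   one window of step directions.
#' @param alpha_global_deg Pairwise angle threshold in degrees
#'   (default 120).
#' @param max_bad_pairs Maximum tolerated bad pairs (default 3).
#' @param pair_mode `"all"` (default; every unordered pair in the
#'   window) or `"consecutive"` (successive steps only).
#' @return `TRUE` to continue growth, `FALSE` to terminate.
#' @export
window_check <- function(step_dirs, alpha_global_deg = 120,
                         max_bad_pairs = 3L,
                         pair_mode = c("all", "consecutive")) {
  pair_mode <- match.arg(pair_mode)
  step_dirs <- rbind(step_dirs)
  w <- nrow(step_dirs)
  if (w < 2) return(TRUE)
  cg <- cos(alpha_global_deg * pi / 180)
  if (pair_mode == "consecutive") {
    d <- rowSums(step_dirs[-w, , drop = FALSE] *
                   step_dirs[-1, , drop = FALSE])
    return(sum(d < cg) <= max_bad_pairs)
  }
  g <- tcrossprod(step_dirs)
  bad <- sum(g[upper.tri(g)] < cg)
  bad <= max_bad_pairs
}

new_microtubule <- function(points, step_um) {
  structure(list(points = points,
                 length_um = (nrow(points) - 1) * step_um,
                 step_um = step_um),
            class = "microtubule")
}

#' @export
print.microtubule <- function(x, ...) {
  cat(sprintf("<microtubule: %d points, length %.2f um>\n",
              nrow(x$points), x$length_um))
  invisible(x)
}

#' Grow a single microtubule
#'
#' Grows a polyline of equally spaced points starting at the centrosome
#' (voxel centre).  The first step direction is uniform on the unit
#' sphere, resampled until the first point is cytosolic; subsequent
#' free steps keep the exact collinearity angle with the previous
#' direction; when the cone step would exit the cytosol, up to
#' `n_rebound_candidates` directions are sampled uniformly within the
#' local cone of half-angle `acos(cos_alpha_local)` and the first
#' cytosolic one is taken.  Growth terminates early when no candidate
#' stays inside, or when the sliding-window curvature rule fires.
#'
#' @param geom A [cell_geometry()].
#' @param params A [growth_params()].
#' @param target_length_um Desired length; a positive multiple of the
#'   step length.
#' @return On success, a `microtubule` (list with `points`, an
#'   `n x 3` matrix of positions in micrometres, and `length_um`).  On
#'   early termination, an object of class `mt_failure` carrying the
#'   partial `points` and `realized_length_um`.
#' @export
grow_microtubule <- function(geom, params, target_length_um) {
  stopifnot(inherits(geom, "cell_geometry"),
            inherits(params, "growth_params"))
  steps <- round(target_length_um / params$step_um)
  if (steps < 1 || abs(steps * params$step_um - target_length_um) > 1e-9)
    stop("target length must be a positive multiple of the step length")
  res <- grow_mt_cpp(
    geom$cytosol, dim(geom$cytosol),
    voxel_centre(geom$centrosome, geom$voxel_size_um, geom$z_step_um),
    geom$voxel_size_um, geom$z_step_um, params$step_um,
    params$collinearity, params$cos_alpha_local,
    cos(params$alpha_global_deg * pi / 180),
    params$window_steps, params$max_bad_pairs,
    if (params$window_pair_mode == "consecutive") 1L else 0L,
    params$n_rebound_candidates, as.integer(steps), 1000L)
  if (res$complete) {
    new_microtubule(res$points, params$step_um)
  } else {
    structure(list(points = res$points,
                   realized_length_um = res$realized_steps * params$step_um),
              class = "mt_failure")
  }
}

#' Generate a full microtubule distribution
#'
#' Samples `n` desired lengths from the Erlang distribution, sorts them
#' from longest to shortest, and grows microtubules so that realized
#' lengths match the sampled lengths exactly: a microtubule that
#' terminates early is stored, keyed by its realized length, and reused
#' when a later desired length matches; each desired length is
#' attempted at most `max_retries` times before the procedure fails.
#'
#' @param geom A [cell_geometry()].
#' @param params A [growth_params()].
#' @return List of `n` `microtubule` objects whose realized-length
#'   multiset equals the sampled desired multiset.
#' @export
generate_distribution <- function(geom, params) {
  lens <- sort(sample_lengths(params$n, params$mu_um,
                              params$erlang_shape_k, params$step_um),
               decreasing = TRUE)
  storage <- new.env(parent = emptyenv())
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    key <- as.character(round(lens[i] / params$step_um))
    bin <- storage[[key]]
    if (!is.null(bin) && length(bin) > 0) {
      out[[i]] <- new_microtubule(bin[[length(bin)]], params$step_um)
      storage[[key]] <- bin[-length(bin)]
      next
    }
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      mt <- grow_microtubule(geom, params, lens[i])
      if (inherits(mt, "microtubule")) { out[[i]] <- mt; break }
      rs <- round(mt$realized_length_um / params$step_um)
      if (rs >= 1) {
        k2 <- as.character(rs)
        storage[[k2]] <- c(storage[[k2]], list(mt$points))
      }
      if (attempts >= params$max_retries)
        stop("input parameters cannot be generated")
    }
  }
  out
}

#' Write a microtubule set to CSV
#'
#' One row per polyline point with columns `mt_id, x, y, z` (positions
#' in micrometres).
#'
#' @param mts List of `microtubule` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microtubules_csv <- function(mts, path) {
  rows <- do.call(rbind, lapply(seq_along(mts), function(i) {
    p <- mts[[i]]$points
    data.frame(mt_id = i, x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  if (is.null(rows))
    rows <- data.frame(mt_id = integer(), x = numeric(),
                       y = numeric(), z = numeric())
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
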