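# Fixtures module: parametric synthetic cell geometries and
# ground-truth image sets, including the simulation-validation
# experiment (validation bed vs independently seeded test libraries).

#' Specification of a synthetic cell geometry
#'
#' A superellipse cell footprint containing an offset elliptical
#' nucleus, extruded to 3D through the same tapering model used for
#' real cells.  The default footprint (40 x 30 um ellipse) is a
#' typical adherent cultured-cell scale, large enough for the full
#' range of library mean lengths to be generable under the curvature
#' rules.
#'
#' @param cell_semiaxes_um Cell footprint semi-axes `(a, b)` in
#'   micrometres.
#' @param cell_exponent Superellipse exponent (2 = ellipse; larger is
#'   boxier).
#' @param nucleus_semiaxes_um Nucleus semi-axes in micrometres.
#' @param nucleus_offset_um Nucleus centre offset from the cell centre.
#' @param height_um Cell height (multiple of `voxel_size_um`).
#' @param voxel_size_um Isotropic lateral voxel size and z step.
#' @param margin_px Background margin around the cell footprint.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(cell_semiaxes_um = c(20, 15),
                         cell_exponent = 2,
                         nucleus_semiaxes_um = c(8, 6),
                         nucleus_offset_um = c(3.5, 0),
                         height_um = 1.6, voxel_size_um = 0.2,
                         margin_px = 2L) {
  stopifnot(all(cell_semiaxes_um > 0), all(nucleus_semiaxes_um > 0),
            height_um > 0, voxel_size_um > 0)
  # nucleus strictly inside the cell footprint (conservative check on
  # the bounding boxes along each axis)
  if (any(abs(nucleus_offset_um) + nucleus_semiaxes_um >=
          cell_semiaxes_um))
    stop("nucleus is not strictly inside the cell")
  structure(list(cell_semiaxes_um = cell_semiaxes_um,
                 cell_exponent = cell_exponent,
                 nucleus_semiaxes_um = nucleus_semiaxes_um,
                 nucleus_offset_um = nucleus_offset_um,
                 height_um = height_um,
                 voxel_size_um = voxel_size_um,
                 margin_px = as.integer(margin_px)),
            class = "fixture_spec")
}

superellipse_mask <- function(centre_um, semiaxes_um, exponent, dims,
                              voxel_size_um) {
  gx <- ((seq_len(dims[1]) - 0.5) * voxel_size_um - centre_um[1]) /
    semiaxes_um[1]
  gy <- ((seq_len(dims[2]) - 0.5) * voxel_size_um - centre_um[2]) /
    semiaxes_um[2]
  outer(abs(gx)^exponent, rep(1, dims[2])) +
    outer(rep(1, dims[1]), abs(gy)^exponent) <= 1
}

#' Bottom shapes of a fixture cell
#'
#' @param spec A [fixture_spec()].
#' @return List with `cell` and `nucleus` [mask2d()] bottom shapes.
#' @export
fixture_bottom_shapes <- function(spec) {
  v <- spec$voxel_size_um
  dims <- 2L * ceiling(spec$cell_semiaxes_um / v) + 2L * spec$margin_px
  centre <- dims / 2 * v
  cell <- superellipse_mask(centre, spec$cell_semiaxes_um,
                            spec$cell_exponent, dims, v)
  nuc <- superellipse_mask(centre + spec$nucleus_offset_um,
                           spec$nucleus_semiaxes_um, 2, dims, v)
  list(cell = mask2d(cell, v), nucleus = mask2d(nuc & cell, v))
}

#' Build a synthetic cell geometry
#'
#' Extrudes the fixture's bottom shapes through [build_volume()] (so
#' fixtures exercise the same tapering code as real cells) and places
#' the centrosome at the central-slice cytosolic voxel nearest the
#' nucleus.  The construction is deterministic.
#'
#' @param spec A [fixture_spec()].
#' @param height_um Optional height override (default the spec's).
#' @return A [cell_geometry()].
#' @export
make_geometry <- function(spec, height_um = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(height_um)) height_um <- spec$height_um
  b <- fixture_bottom_shapes(spec)
  geometry_for_height(b$cell, b$nucleus, height_um, spec$voxel_size_um)
}

fixture_geometries <- function(spec, height_values) {
  geoms <- list()
  for (h in height_values)
    geoms[[as.character(h)]] <- make_geometry(spec, h)
  geoms
}

#' Generate a labelled ground-truth image set
#'
#' One central-slice image per grid point, with the true generation
#' parameters and the per-entry seed recorded.
#'
#' @param spec A [fixture_spec()].
#' @param grid A [parameter_grid()].
#' @param seed Base seed; entry seeds are `seed + entry index`.
#' @param cfg A [library_config()].
#' @return List with `images` (list of [image2d()]), `params` (data
#'   frame of true parameters and seeds) and the underlying
#'   `library_index`.
#' @export
make_ground_truth_set <- function(spec, grid, seed = 1L,
                                  cfg = library_config()) {
  geoms <- fixture_geometries(spec, grid$height_values)
  cfg_all <- cfg
  cfg_all$max_failure_fraction <- 1   # report points, not an abort
  lib <- build_library_core(geoms, grid, seed, cfg_all)
  if (nrow(lib$failures) > 0)
    stop("ground-truth generation failed at grid point(s): ",
         paste(sprintf("(n=%d, mu=%g, cos=%g)", lib$failures$n,
                       lib$failures$mu_um, lib$failures$collinearity),
               collapse = "; "))
  list(images = lib$images, params = lib$entries, library = lib)
}

#' Simulation-validation experiment
#'
#' Replicates the synthetic parameter-recovery protocol: on one cell
#' geometry, a validation bed of images with known parameters is
#' generated, followed by `n_test_libraries` further libraries with
#' different random seeds; every validation image is matched into each
#' test library and the mean absolute percentage error of each
#' recovered parameter is reported per test library, with the spread
#' (standard deviation) of the per-image absolute percentage errors.
#'
#' @param spec A [fixture_spec()].
#' @param grid A [parameter_grid()].
#' @param n_test_libraries Number of independently seeded test
#'   libraries (default 5).
#' @param seed Base seed `s0`; the bed uses `s0` and test library `t`
#'   uses `s0 + t`, with a stride applied to the derived per-entry
#'   seeds so that streams never coincide across libraries.
#' @param cfg A [library_config()].
#' @return Data frame with one row per test library and columns
#'   `library`, `mape_n`, `sd_ape_n`, `mape_mu`, `sd_ape_mu`,
#'   `mape_collinearity`, `sd_ape_collinearity`.  The per-image
#'   estimates are attached as attribute `details`.
#' @export
validation_experiment <- function(spec, grid, n_test_libraries = 5L,
                                  seed = 1L, cfg = library_config()) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(grid, "parameter_grid"))
  geoms <- fixture_geometries(spec, grid$height_values)
  stride <- grid_size(grid) + 1000L
  bed <- build_library_core(geoms, grid, seed * stride, cfg)
  out <- vector("list", n_test_libraries)
  details <- vector("list", n_test_libraries)
  for (t in seq_len(n_test_libraries)) {
    lib <- build_library_core(geoms, grid, (seed + t) * stride, cfg)
    est <- lapply(seq_len(nrow(bed$entries)), function(i)
      match_library(bed$features[i, ], lib))
    true_n <- bed$entries$n
    true_mu <- bed$entries$mu_um
    true_c <- bed$entries$collinearity
    est_n <- vapply(est, `[[`, 0, "n")
    est_mu <- vapply(est, `[[`, 0, "mu_um")
    est_c <- vapply(est, `[[`, 0, "collinearity")
    out[[t]] <- data.frame(
      library = t,
      mape_n = mape(true_n, est_n),
      sd_ape_n = sd(ape(true_n, est_n)),
      mape_mu = mape(true_mu, est_mu),
      sd_ape_mu = sd(ape(true_mu, est_mu)),
      mape_collinearity = mape(true_c, est_c),
      sd_ape_collinearity = sd(ape(true_c, est_c)))
    details[[t]] <- data.frame(library = t, true_n = true_n,
                               est_n = est_n, true_mu = true_mu,
                               est_mu = est_mu, true_collinearity = true_c,
                               est_collinearity = est_c)
  }
  res <- do.call(rbind, out)
  attr(res, "details") <- do.call(rbind, details)
  res
}

#' The reduced validation grid
#'
#' A 32-point grid (4 counts x 4 mean lengths x 2 collinearity values
#' x 1 height) spanning the standard grid's range, used for the
#' desk-scale validation experiment.
#'
#' @return A [parameter_grid()].
#' @export
reduced_grid <- function() {
  parameter_grid(n_values = c(50L, 150L, 250L, 350L),
                 mu_values = c(10, 20, 30, 40),
                 collinearity_values = c(0.97, 0.9961),
                 height_values = 1.6)
}
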