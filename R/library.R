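# Library module: the per-cell grid of synthetic images used for
# matching.

LIBRARY_SCHEMA_VERSION <- 1L

#' Parameter grid for library generation
#'
#' @param n_values Integer microtubule counts.
#' @param mu_values Mean lengths in micrometres.
#' @param collinearity_values Collinearity (cos alpha) values in
#'   (0, 1].
#' @param height_values Cell heights in micrometres.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(n_values, mu_values, collinearity_values,
                           height_values) {
  stopifnot(length(n_values) > 0, length(mu_values) > 0,
            length(collinearity_values) > 0, length(height_values) > 0,
            all(n_values >= 0), all(mu_values > 0),
            all(collinearity_values > 0), all(collinearity_values <= 1),
            all(height_values > 0))
  structure(list(n_values = as.integer(n_values),
                 mu_values = as.numeric(mu_values),
                 collinearity_values = as.numeric(collinearity_values),
                 height_values = as.numeric(height_values)),
            class = "parameter_grid")
}

#' Number of parameter combinations in a grid
#' @param grid A [parameter_grid()].
#' @return Integer combination count.
#' @export
grid_size <- function(grid) {
  length(grid$n_values) * length(grid$mu_values) *
    length(grid$collinearity_values) * length(grid$height_values)
}

# all combinations in deterministic order: height slowest, then
# collinearity, mu, n fastest
grid_table <- function(grid) {
  g <- expand.grid(n = grid$n_values, mu_um = grid$mu_values,
                   collinearity = grid$collinearity_values,
                   height_um = grid$height_values,
                   KEEP.OUT.ATTRS = FALSE)
  g$entry_id <- seq_len(nrow(g))
  g
}

#' The standard library parameter grid
#'
#' Ten microtubule counts, nine mean lengths, three collinearity
#' values and three cell heights: 810 combinations.
#'
#' @return A [parameter_grid()].
#' @export
default_grid <- function() {
  parameter_grid(
    n_values = c(5L, 50L, 100L, 150L, 200L, 250L, 300L, 350L, 400L, 450L),
    mu_values = seq(5, 45, by = 5),
    collinearity_values = c(0.97000, 0.98466, 0.99610),
    height_values = c(1.2, 1.4, 1.6))
}

#' Configuration for library generation
#'
#' @param erlang_shape_k Erlang shape for length sampling (default 2).
#' @param step_um Growth step (default 0.2).
#' @param single_mt_intensity Intensity scale applied after PSF
#'   convolution, in gray levels per filament-crossing (default 20, a
#'   typical single-filament brightness in 8-bit confocal tubulin
#'   images; the centrosomal aster saturates, as in real data).
#'   Matching is intensity-consistent as long as queries and library
#'   share the scale.
#' @param psf_sigma_px Optional PSF sigma override in voxels.
#' @param quantize_8bit Quantize synthetic slices to 8 bits (default
#'   `TRUE`, emulating the 8-bit TIFF acquisition the method targets;
#'   the fixed 0-255 range also stabilizes the min-max binned texture
#'   and gradient-histogram features).
#' @param max_failure_fraction Abort library generation when more than
#'   this fraction of grid points cannot be generated (default 0.5).
#' @return An object of class `library_config`.
#' @export
library_config <- function(erlang_shape_k = 2L, step_um = 0.2,
                           single_mt_intensity = 20,
                           psf_sigma_px = NULL, quantize_8bit = TRUE,
                           max_failure_fraction = 0.5) {
  structure(list(erlang_shape_k = as.integer(erlang_shape_k),
                 step_um = step_um,
                 single_mt_intensity = single_mt_intensity,
                 psf_sigma_px = psf_sigma_px,
                 quantize_8bit = quantize_8bit,
                 max_failure_fraction = max_failure_fraction),
            class = "library_config")
}

# geometry for one height from bottom masks
geometry_for_height <- function(bottom_cell, bottom_nucleus, height_um,
                                z_step_um = 0.2, centrosome_xy = NULL) {
  cellv <- build_volume(bottom_cell, height_um, z_step_um, "cell")
  nucv <- build_volume(bottom_nucleus, height_um, z_step_um, "nucleus")
  nucv$voxels <- nucv$voxels & cellv$voxels
  kz <- floor(dim(cellv$voxels)[3] / 2)
  if (is.null(centrosome_xy)) {
    geom0 <- assemble_geometry(cellv, nucv,
                               centrosome_guess(cellv, nucv, kz))
    return(geom0)
  }
  assemble_geometry(cellv, nucv, c(centrosome_xy, kz))
}

centrosome_guess <- function(cellv, nucv, kz) {
  cyt <- cellv$voxels[, , kz + 1L] & !nucv$voxels[, , kz + 1L]
  nuc <- nucv$voxels[, , kz + 1L]
  if (!any(cyt)) stop("no cytosol at the central slice")
  dn <- if (any(nuc)) imageData(EBImage::distmap(ebimg(!nuc)))
        else matrix(0, nrow(cyt), ncol(cyt))
  dn[!cyt] <- Inf
  i <- which.min(dn)
  c((i - 1L) %% nrow(cyt), (i - 1L) %/% nrow(cyt), kz)
}

# core generation loop over prebuilt geometries (one per height)
build_library_core <- function(geoms, grid, base_seed, cfg) {
  tab <- grid_table(grid)
  feats <- NULL
  images <- vector("list", nrow(tab))
  ok <- logical(nrow(tab))
  fail_msg <- character(nrow(tab))
  psf_cache <- list()
  for (i in seq_len(nrow(tab))) {
    h <- as.character(tab$height_um[i])
    geom <- geoms[[h]]
    if (is.null(psf_cache[[h]]))
      psf_cache[[h]] <- make_psf(geom$voxel_size_um, geom$z_step_um,
                                 sigma_px = cfg$psf_sigma_px)
    set.seed(base_seed + tab$entry_id[i])
    params <- growth_params(tab$n[i], tab$mu_um[i], tab$collinearity[i],
                            erlang_shape_k = cfg$erlang_shape_k,
                            step_um = cfg$step_um)
    mts <- tryCatch(generate_distribution(geom, params),
                    error = function(e) e)
    if (inherits(mts, "error")) {
      fail_msg[i] <- conditionMessage(mts)
      next
    }
    vol <- render(mts, geom)
    vol <- apply_optics(vol, psf_cache[[h]], cfg$single_mt_intensity,
                        pad = TRUE, quantize_8bit = cfg$quantize_8bit)
    sl <- central_slice(vol)
    cmask <- central_slice(geom$cell)
    f <- compute_features(sl, cmask, geom$centrosome[1:2])
    if (is.null(feats)) feats <- matrix(NA_real_, nrow(tab), length(f),
                                        dimnames = list(NULL, names(f)))
    feats[i, ] <- f
    images[[i]] <- sl
    ok[i] <- TRUE
  }
  if (mean(!ok) > cfg$max_failure_fraction)
    stop("geometry cannot support the grid: ",
         sum(!ok), " of ", nrow(tab), " grid points failed")
  if (is.null(feats))   # every grid point failed (tolerated by cfg)
    feats <- matrix(NA_real_, nrow(tab), length(feature_names()),
                    dimnames = list(NULL, feature_names()))
  entries <- tab[ok, , drop = FALSE]
  entries$seed <- base_seed + entries$entry_id
  rownames(entries) <- NULL
  feats <- feats[ok, , drop = FALSE]
  sds <- apply(feats, 2L, sd)
  sds[!is.finite(sds)] <- 0   # single-entry libraries have no spread
  ns <- list(mean = colMeans(feats), sd = sds)
  failures <- data.frame(entry_id = tab$entry_id[!ok],
                         n = tab$n[!ok], mu_um = tab$mu_um[!ok],
                         collinearity = tab$collinearity[!ok],
                         height_um = tab$height_um[!ok],
                         message = fail_msg[!ok])
  structure(list(entries = entries, features = feats, norm_stats = ns,
                 failures = failures, images = images[ok],
                 grid = grid, base_seed = base_seed, cfg = cfg,
                 geoms = geoms,
                 schema_version = LIBRARY_SCHEMA_VERSION),
            class = "library_index")
}

#' Build a synthetic-image library for one cell geometry
#'
#' For each height in the grid the 3D cell and nuclear morphology is
#' extruded once from the bottom shapes; for every parameter
#' combination a microtubule distribution is generated (seeded with
#' `base_seed` + entry index, so entries are independent of execution
#' order), rendered, passed through the optical model, and summarized
#' by the central-slice feature vector.  Grid points whose parameters
#' cannot be generated in this geometry are recorded as failures and
#' excluded from matching.
#'
#' @param bottom_cell,bottom_nucleus [mask2d()] bottom shapes.
#' @param grid A [parameter_grid()].
#' @param base_seed Integer seed.
#' @param cfg A [library_config()].
#' @param centrosome_xy Optional 0-based `(x, y)`; by default the
#'   centrosome is placed at the central-slice cytosolic voxel nearest
#'   the nucleus.
#' @param z_step_um Slice spacing (default 0.2).
#' @return A `library_index`: entry table (params + seeds), feature
#'   matrix, per-feature normalization statistics, failure table and
#'   the central-slice images.
#' @export
build_library <- function(bottom_cell, bottom_nucleus, grid,
                          base_seed = 1L, cfg = library_config(),
                          centrosome_xy = NULL, z_step_um = 0.2) {
  stopifnot(inherits(grid, "parameter_grid"))
  geoms <- list()
  for (h in grid$height_values)
    geoms[[as.character(h)]] <-
      geometry_for_height(bottom_cell, bottom_nucleus, h, z_step_um,
                          centrosome_xy)
  build_library_core(geoms, grid, base_seed, cfg)
}

#' @export
print.library_index <- function(x, ...) {
  cat(sprintf("<library_index: %d entries, %d failures, %d features>\n",
              nrow(x$entries), nrow(x$failures), ncol(x$features)))
  invisible(x)
}

#' Save a library to disk
#'
#' Central-slice images as one TIFF per entry, the index (parameters,
#' seeds, normalization statistics, full-precision features, config)
#' as JSON, plus a human-readable features CSV.
#'
#' @param index A `library_index`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_library <- function(index, path) {
  stopifnot(inherits(index, "library_index"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "images"), showWarnings = FALSE)
  scale_max <- numeric(nrow(index$entries))
  for (i in seq_len(nrow(index$entries))) {
    img <- index$images[[i]]
    f <- file.path(path, "images",
                   sprintf("entry_%04d.tif", index$entries$entry_id[i]))
    scale_max[i] <- max(img$pixels, 1e-12)
    tiff::writeTIFF(pmin(t(img$pixels) / scale_max[i], 1), f,
                    bits.per.sample = 32L)
  }
  meta <- list(schema_version = index$schema_version,
               base_seed = index$base_seed,
               grid = unclass(index$grid),
               cfg = unclass(index$cfg),
               entries = index$entries,
               scale_max = scale_max,
               feature_names = colnames(index$features),
               features = unname(apply(index$features, 1L, as.numeric,
                                       simplify = FALSE)),
               norm_stats = list(mean = unname(index$norm_stats$mean),
                                 sd = unname(index$norm_stats$sd)),
               failures = index$failures,
               pixel_size_um = index$images[[1]]$pixel_size_um)
  jsonlite::write_json(meta, file.path(path, "index.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  fcsv <- cbind(index$entries, as.data.frame(index$features))
  write.csv(fcsv, file.path(path, "features.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a library saved with [save_library()]
#'
#' @param path Library directory.
#' @return A `library_index` (without in-memory geometries).
#' @export
load_library <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "index.json"),
                              simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), LIBRARY_SCHEMA_VERSION))
    stop("library schema version mismatch: found ", meta$schema_version,
         ", expected ", LIBRARY_SCHEMA_VERSION)
  feats <- meta$features
  if (is.list(feats)) feats <- do.call(rbind, feats)
  feats <- as.matrix(feats)
  dimnames(feats) <- list(NULL, meta$feature_names)
  entries <- as.data.frame(meta$entries)
  images <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    f <- file.path(path, "images",
                   sprintf("entry_%04d.tif", entries$entry_id[i]))
    if (!file.exists(f)) stop("missing library image file: ", f)
    images[[i]] <- image2d(t(tiff::readTIFF(f)) * meta$scale_max[i],
                           meta$pixel_size_um)
  }
  ns <- list(mean = stats::setNames(meta$norm_stats$mean,
                                    meta$feature_names),
             sd = stats::setNames(meta$norm_stats$sd,
                                  meta$feature_names))
  grid <- parameter_grid(meta$grid$n_values, meta$grid$mu_values,
                         meta$grid$collinearity_values,
                         meta$grid$height_values)
  cfg <- do.call(library_config, meta$cfg[!vapply(meta$cfg, is.null,
                                                  TRUE)])
  failures <- as.data.frame(meta$failures)
  structure(list(entries = entries, features = feats, norm_stats = ns,
                 failures = failures, images = images, grid = grid,
                 base_seed = meta$base_seed, cfg = cfg, geoms = NULL,
                 schema_version = as.integer(meta$schema_version)),
            class = "library_index")
}
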