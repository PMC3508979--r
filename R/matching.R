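# Matching module: 2D image features and nearest-library-image
# parameter estimation.

haralick_names <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy",
                    "entropy", "diff_variance", "diff_entropy",
                    "imc1", "imc2")

#' Feature names of the default feature set
#'
#' 13 Haralick co-occurrence texture features (distance 1, average of
#' the 4 directions, 64 gray levels from in-mask min-max binning),
#' Prewitt edge features (8-bin normalized gradient-magnitude
#' histogram over `[0, max]`, 8-bin magnitude-weighted
#' gradient-direction histogram over 45-degree sectors, edge-pixel
#' fraction, total gradient magnitude), in-mask intensity total, mean
#' and variance, and the intensity-weighted mean distance to the
#' centrosome normalized by the maximum in-mask distance.
#'
#' @return Character vector of length 35, in feature-vector order.
#' @export
feature_names <- function() {
  c(paste0("har_", haralick_names),
    paste0("grad_mag_h", 1:8),
    paste0("grad_dir_h", 1:8),
    "edge_fraction", "grad_total",
    "int_total", "int_mean", "int_var",
    "cdist_mean")
}

#' Compute the 2D feature vector of a cell image
#'
#' See [feature_names()] for the feature set.  For a constant in-mask
#' image the gradient magnitude histogram places all mass in the first
#' bin, the direction histogram is all zeros, and co-occurrence
#' features that are undefined on a single gray level (e.g. the
#' correlation) are set to 0, so the vector is always finite.
#'
#' @param img An [image2d()].
#' @param mask A nonempty [mask2d()] restricting all features.
#' @param centrosome_xy Integer 0-based `(x, y)` pixel coordinates of
#'   the centrosome.
#' @return Named numeric vector of length 35.
#' @export
compute_features <- function(img, mask, centrosome_xy) {
  stopifnot(inherits(img, "image2d"), inherits(mask, "mask2d"),
            identical(dim(img$pixels), dim(mask$voxels)))
  if (!any(mask$voxels)) stop("empty mask")
  px <- img$pixels
  m <- mask$voxels

  # Haralick texture: in-mask min-max scaled to [0,1], 64 bins, scale 1
  inm <- px[m]
  rng <- range(inm)
  sc <- px * 0
  if (rng[2] > rng[1]) sc[m] <- (px[m] - rng[1]) / (rng[2] - rng[1])
  har <- EBImage::computeFeatures.haralick(ebimg(m), ebimg(sc),
                                           haralick.nbins = 64L,
                                           haralick.scales = 1L)
  har <- as.numeric(har)
  har[!is.finite(har)] <- 0

  # Prewitt gradients
  kx <- matrix(c(-1, 0, 1), 3L, 3L)  # d/dx (x = first array index)
  ky <- t(kx)
  gx <- imageData(EBImage::filter2(ebimg(px), kx))
  gy <- imageData(EBImage::filter2(ebimg(px), ky))
  mag <- sqrt(gx^2 + gy^2)
  magm <- mag[m]
  mmax <- max(magm)
  if (mmax > 0) {
    br <- seq(0, mmax, length.out = 9L)
    hmag <- hist_counts(magm, br) / length(magm)
    ang <- atan2(gy[m], gx[m]) %% (2 * pi)
    sector <- pmin(floor(ang / (pi / 4)), 7) + 1L
    hdir <- vapply(1:8, function(s) sum(magm[sector == s]), 0.0)
    hdir <- hdir / sum(magm)
  } else {
    hmag <- c(1, rep(0, 7))
    hdir <- rep(0, 8)
  }
  edge_fraction <- if (mmax > 0) mean(magm > mean(magm)) else 0
  grad_total <- sum(magm)

  # intensity and centrosome-referenced features
  d <- dim(px)
  dx <- (seq_len(d[1]) - 1L) - centrosome_xy[1]
  dy <- (seq_len(d[2]) - 1L) - centrosome_xy[2]
  dist <- sqrt(outer(dx^2, rep(1, d[2])) + outer(rep(1, d[1]), dy^2))
  dm <- dist[m]
  tot <- sum(inm)
  cdist <- if (tot > 0 && max(dm) > 0) sum(inm * dm) / tot / max(dm) else 0

  v <- c(har, hmag, hdir, edge_fraction, grad_total,
         tot, mean(inm), var_n1(inm), cdist)
  names(v) <- feature_names()
  v
}

hist_counts <- function(x, breaks) {
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              length(breaks) - 1L)
  tabulate(idx, nbins = length(breaks) - 1L)
}

var_n1 <- function(x) if (length(x) < 2) 0 else stats::var(x)

#' Normalized Euclidean distance between feature vectors
#'
#' Each feature difference is divided by the library's per-feature
#' standard deviation before the Euclidean norm; features with zero
#' library variance carry no signal within the library and are
#' skipped.
#'
#' @param a,b Named feature vectors with identical names.
#' @param norm_stats List with numeric `mean` and `sd` components as
#'   stored in a library index.
#' @return Nonnegative scalar distance.
#' @export
normalized_distance <- function(a, b, norm_stats) {
  if (!identical(names(a), names(b)) ||
      !identical(names(a), names(norm_stats$sd)))
    stop("mismatched feature names")
  keep <- norm_stats$sd > 0
  sqrt(sum(((a[keep] - b[keep]) / norm_stats$sd[keep])^2))
}

#' Match a query feature vector against a library
#'
#' Returns the library entry minimizing the normalized Euclidean
#' distance; the matched entry's generation parameters are the
#' estimates.  Ties break to the smallest entry id.
#'
#' @param query Named feature vector from [compute_features()].
#' @param lib A `library_index` from [build_library()].
#' @return A list of class `match_result` with fields `entry_id`, `n`,
#'   `mu_um`, `collinearity`, `height_um` and `distance`.
#' @export
match_library <- function(query, lib) {
  stopifnot(inherits(lib, "library_index"))
  if (nrow(lib$entries) == 0) stop("empty library")
  keep <- lib$norm_stats$sd > 0
  z <- sweep(lib$features[, keep, drop = FALSE], 2L, query[keep], "-")
  z <- sweep(z, 2L, lib$norm_stats$sd[keep], "/")
  dist <- sqrt(rowSums(z^2))
  i <- which.min(dist)  # first minimum = smallest entry id
  e <- lib$entries[i, ]
  structure(list(entry_id = e$entry_id, n = e$n, mu_um = e$mu_um,
                 collinearity = e$collinearity, height_um = e$height_um,
                 distance = dist[i]),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("<match: entry %d, n = %d, mu = %.3g um, ",
                     "cos alpha = %.5g, height = %.3g um, dist = %.4g>\n"),
              x$entry_id, x$n, x$mu_um, x$collinearity, x$height_um,
              x$distance))
  invisible(x)
}

#' Estimate microtubule model parameters for a two-channel image
#'
#' End-to-end pipeline for a real (or realistically synthetic)
#' two-channel field: segment the cell, recover the bottom shapes,
#' build (or reuse) the per-cell synthetic library, compute the query
#' features on the tubulin slice, and match.
#'
#' @param tubulin,nuclei [image2d()] channels acquired at half the
#'   cell height.
#' @param grid A [parameter_grid()] (default [default_grid()]).
#' @param base_seed Integer seed for library generation.
#' @param cfg Optional [library_config()].
#' @param cell_index Which segmented cell to estimate (default 1).
#' @param library Optional prebuilt `library_index` to match against
#'   instead of building one.
#' @return A `match_result` with attributes `provenance` (seed, grid
#'   size) and `query_features`.
#' @export
estimate_cell <- function(tubulin, nuclei, grid = default_grid(),
                          base_seed = 1L, cfg = library_config(),
                          cell_index = 1L, library = NULL) {
  cells <- segment_field(tubulin, nuclei)
  if (length(cells) == 0) stop("segmentation found no cells")
  if (cell_index > length(cells)) stop("cell_index out of range")
  cellmask <- cells[[cell_index]]$cell
  nucmask <- cells[[cell_index]]$nucleus
  tub_cell <- image2d(tubulin$pixels * cellmask$voxels,
                      tubulin$pixel_size_um)
  bottom_cell <- bottom_shape(tub_cell)
  bottom_nuc <- mask2d(imageData(EBImage::fillHull(ebimg(nucmask$voxels))) > 0,
                       nuclei$pixel_size_um)
  cxy <- detect_centrosome_xy(tub_cell, bottom_nuc, cell = bottom_cell)
  if (is.null(library))
    library <- build_library(bottom_cell, bottom_nuc, grid, base_seed,
                             cfg, centrosome_xy = cxy)
  q <- compute_features(tub_cell, bottom_cell, cxy)
  res <- match_library(q, library)
  attr(res, "provenance") <- list(base_seed = base_seed,
                                  grid_points = nrow(library$entries),
                                  library_failures = nrow(library$failures))
  attr(res, "query_features") <- q
  res
}
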