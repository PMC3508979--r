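# Geometry module: single-cell segmentation, approximate 3D morphology
# from one 2D slice, and centrosome localization.

ebimg <- function(m) EBImage::Image(m * 1)

#' Segment single cells from a two-channel field image
#'
#' Splits a field of view into single-cell regions by seeded region
#' growing on the tubulin channel, using the labelled nuclei from the
#' nuclear channel as seeds (the seeded-watershed contract: one region
#' per nucleus, regions disjoint, each nucleus inside its region).
#'
#' @param tubulin,nuclei [image2d()] channels of identical shape and
#'   pixel size.
#' @param nucleus_threshold,cell_threshold Intensity thresholds for the
#'   nuclear and cell foreground; `NULL` (default) uses Otsu's method on
#'   each channel.
#' @param min_nucleus_px Nuclei smaller than this are discarded as
#'   segmentation debris.
#' @return A list with one element per detected nucleus, each a list
#'   with components `cell` and `nucleus` ([mask2d()] objects).  An
#'   empty list (with a warning) when no nuclei are found.
#' @export
segment_field <- function(tubulin, nuclei, nucleus_threshold = NULL,
                          cell_threshold = NULL, min_nucleus_px = 20L) {
  stopifnot(inherits(tubulin, "image2d"), inherits(nuclei, "image2d"))
  if (!identical(dim(tubulin$pixels), dim(nuclei$pixels)) ||
      tubulin$pixel_size_um != nuclei$pixel_size_um)
    stop("channels must share shape and pixel size")
  nt <- if (is.null(nucleus_threshold)) otsu_threshold(nuclei$pixels)
        else nucleus_threshold
  ct <- if (is.null(cell_threshold)) otsu_threshold(tubulin$pixels)
        else cell_threshold
  seeds <- EBImage::bwlabel(ebimg(nuclei$pixels > nt))
  keep <- which(tabulate(seeds[seeds > 0]) >= min_nucleus_px)
  seeds[!(seeds %in% keep)] <- 0
  seeds <- EBImage::bwlabel(seeds > 0)  # relabel 1..k
  k <- max(seeds)
  if (k == 0) {
    warning("no nuclei detected; returning empty segmentation")
    return(list())
  }
  fg <- ebimg((tubulin$pixels > ct) | (seeds > 0))
  regions <- EBImage::propagate(ebimg(tubulin$pixels), seeds, mask = fg)
  lapply(seq_len(k), function(i) {
    list(cell = mask2d(imageData(regions) == i, tubulin$pixel_size_um),
         nucleus = mask2d(imageData(seeds) == i, tubulin$pixel_size_um))
  })
}

imageData <- EBImage::imageData

otsu_threshold <- function(px) {
  r <- range(px)
  if (r[1] == r[2]) return(r[1])
  EBImage::otsu(ebimg((px - r[1]) / (r[2] - r[1])), range = c(0, 1)) *
    (r[2] - r[1]) + r[1]
}

#' Bottom shape of a cell from a single-cell tubulin slice
#'
#' The central slice of a cell contains out-of-focus light from the
#' substrate-attached bottom of the cell, so the cell's bottom outline
#' is recovered by thresholding above-background pixels, keeping the
#' largest connected component and filling holes.
#'
#' @param tubulin_cell [image2d()] of a single segmented cell
#'   (background ~ 0 outside the cell).
#' @param threshold Background threshold; pixels strictly above it are
#'   foreground (default 0).
#' @return A [mask2d()].
#' @export
bottom_shape <- function(tubulin_cell, threshold = 0) {
  stopifnot(inherits(tubulin_cell, "image2d"))
  fg <- tubulin_cell$pixels > threshold
  if (!any(fg)) stop("empty cell: no pixels above threshold")
  lab <- EBImage::bwlabel(ebimg(fg))
  big <- which.max(tabulate(lab[lab > 0]))
  m <- EBImage::fillHull(ebimg(imageData(lab) == big))
  mask2d(imageData(m) > 0, tubulin_cell$pixel_size_um)
}

#' Cell area decay with height
#'
#' The slice area of an adherent cell decays with height above the
#' substrate as `A(z) = 2^(-z) * Area`, with `z` in micrometres and
#' `Area` the pixel area of the bottom slice.
#'
#' @param bottom_area_px Pixel area of the bottom slice (> 0).
#' @param z_um Height above the bottom slice in micrometres (>= 0).
#' @return Expected slice area in pixels at height `z_um`.
#' @export
area_profile <- function(bottom_area_px, z_um) {
  stopifnot(bottom_area_px > 0)
  if (any(z_um < 0)) stop("z_um must be nonnegative")
  2^(-z_um) * bottom_area_px
}

# signed distance transform: negative inside the mask, positive outside
signed_distance <- function(m) {
  inside <- EBImage::distmap(ebimg(m))
  outside <- EBImage::distmap(ebimg(!m))
  imageData(outside) - imageData(inside)
}

#' Interpolate between two nested 2D shapes at a target area
#'
#' Convex combination of the signed distance transforms of `bottom` and
#' `top`, thresholded at zero; the mixing weight is found by bisection
#' so the interpolated shape's pixel area matches `target_area_px`
#' within 1%.  Weight 0 reproduces `bottom` and weight 1 reproduces
#' `top` exactly.
#'
#' @param bottom,top [mask2d()] objects, `top` (weakly) inside
#'   `bottom`'s region and no larger.
#' @param target_area_px Target pixel area, between the two mask areas.
#' @param tol Relative area tolerance of the bisection (default 0.01).
#' @return A [mask2d()].
#' @export
interpolate_shape <- function(bottom, top, target_area_px, tol = 0.01) {
  stopifnot(inherits(bottom, "mask2d"), inherits(top, "mask2d"),
            identical(dim(bottom$voxels), dim(top$voxels)))
  ab <- mask_area(bottom); at <- mask_area(top)
  if (target_area_px > ab || target_area_px < at)
    stop("target area outside [area(top), area(bottom)]")
  if (target_area_px == ab) return(bottom)
  if (target_area_px == at) return(top)
  sb <- signed_distance(bottom$voxels)
  st <- signed_distance(top$voxels)
  shape_at <- function(t) ((1 - t) * sb + t * st) < 0
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    a <- sum(shape_at(mid))
    if (abs(a - target_area_px) <= tol * target_area_px) break
    # area decreases as t grows (top smaller than bottom)
    if (a > target_area_px) lo <- mid else hi <- mid
  }
  mask2d(shape_at(mid), bottom$pixel_size_um)
}

# inner "top" ellipse with the bottom shape's centroid, orientation and
# axis ratio (from second moments), at the given pixel area
inner_ellipse <- function(bottom, area_px) {
  idx <- which(bottom$voxels, arr.ind = TRUE) - 0.5  # pixel centres
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  mxx <- mean((idx[, 1] - cx)^2); myy <- mean((idx[, 2] - cy)^2)
  mxy <- mean((idx[, 1] - cx) * (idx[, 2] - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE)
  ratio <- sqrt(max(ev$values) / max(ev$values[2], .Machine$double.eps))
  # semi-axes a >= b with a/b = ratio and pi*a*b = area
  b <- sqrt(area_px / (pi * ratio)); a <- ratio * b
  u <- ev$vectors[, 1]  # major-axis direction
  d <- dim(bottom$voxels)
  gx <- (seq_len(d[1]) - 0.5) - cx
  gy <- (seq_len(d[2]) - 0.5) - cy
  X <- outer(gx, rep(1, d[2])); Y <- outer(rep(1, d[1]), gy)
  p <- X * u[1] + Y * u[2]   # along major axis
  q <- -X * u[2] + Y * u[1]  # along minor axis
  mask2d(((p / a)^2 + (q / b)^2 <= 1) & bottom$voxels,
         bottom$pixel_size_um)
}

#' Extrude a bottom shape into an approximate 3D morphology
#'
#' Builds a 3D mask whose slice `k` (z = k * z_step, bottom slice k = 0)
#' is the distance-transform interpolation between the bottom shape and
#' a smaller inner ellipse, targeting the area profile
#' `A(z) = 2^(-z) * Area`.  The inner ellipse shares the bottom shape's
#' centroid, orientation and axis ratio and has area `A(height)`.
#'
#' @param bottom [mask2d()] bottom shape.
#' @param height_um Cell height in micrometres; a positive multiple of
#'   `z_step_um`.
#' @param z_step_um Slice spacing (default 0.2).
#' @param channel `"cell"` or `"nucleus"` (metadata only; both channels
#'   use the same extrusion).
#' @return A [mask3d()] with `height_um / z_step_um` slices and weakly
#'   decreasing slice areas.
#' @export
build_volume <- function(bottom, height_um, z_step_um = 0.2,
                         channel = c("cell", "nucleus")) {
  channel <- match.arg(channel)
  stopifnot(inherits(bottom, "mask2d"), height_um > 0)
  nz <- round(height_um / z_step_um)
  if (nz < 1 || abs(nz * z_step_um - height_um) > 1e-9)
    stop("height_um must be a positive multiple of z_step_um")
  area0 <- mask_area(bottom)
  a_top <- area_profile(area0, height_um)
  if (a_top < 1) stop("area profile drops below one pixel at this height")
  d <- dim(bottom$voxels)
  vox <- array(FALSE, c(d, nz))
  if (nz == 1L) {
    vox[, , 1] <- bottom$voxels
    return(mask3d(vox, bottom$pixel_size_um, z_step_um))
  }
  top <- inner_ellipse(bottom, a_top)
  prev_area <- Inf
  for (k in seq_len(nz) - 1L) {
    target <- min(area_profile(area0, k * z_step_um), prev_area)
    sl <- if (k == 0L) bottom
          else interpolate_shape(bottom, top, max(target, mask_area(top)))
    # enforce weak monotonicity against interpolation tolerance
    if (sum(sl$voxels) > prev_area && k > 0L)
      sl$voxels <- sl$voxels & vox[, , k]
    vox[, , k + 1L] <- sl$voxels
    prev_area <- sum(sl$voxels)
  }
  mask3d(vox, bottom$pixel_size_um, z_step_um)
}

#' Locate the centrosome in XY
#'
#' The centrosome appears as the brightest tubulin spot near the
#' nucleus: the tubulin channel is smoothed with a 25 x 25 averaging
#' filter and the argmax is taken over the vicinity of the nucleus (the
#' nucleus mask dilated by the smoothing scale, intersected with the
#' cell mask when given).  Ties break to the first pixel in array
#' order (x fastest), deterministically.
#'
#' @param tubulin_cell [image2d()] single-cell tubulin image.
#' @param nucleus [mask2d()] nucleus mask.
#' @param cell Optional [mask2d()] cell mask bounding the vicinity.
#' @param filter_px Averaging-filter width in pixels (default 25).
#' @return Integer 0-based pixel coordinates `c(x, y)`.
#' @export
detect_centrosome_xy <- function(tubulin_cell, nucleus, cell = NULL,
                                 filter_px = 25L) {
  stopifnot(inherits(tubulin_cell, "image2d"), inherits(nucleus, "mask2d"))
  if (!any(nucleus$voxels)) stop("empty nucleus mask")
  box <- EBImage::makeBrush(filter_px, shape = "box")
  sm <- imageData(EBImage::filter2(ebimg(tubulin_cell$pixels),
                                   box / sum(box)))
  disc <- EBImage::makeBrush(2L * filter_px + 1L, shape = "disc")
  vic <- imageData(EBImage::dilate(ebimg(nucleus$voxels), disc)) > 0
  if (!is.null(cell)) vic <- vic & cell$voxels
  if (!any(vic)) stop("empty vicinity region")
  sm[!vic] <- -Inf
  i <- which.max(sm)  # first occurrence in array order on ties
  d <- dim(sm)
  c(x = (i - 1L) %% d[1], y = (i - 1L) %/% d[1])
}

#' Linear model for the centrosome z coordinate
#'
#' @param coefficients Numeric vector of 4 finite coefficients:
#'   intercept, then weights for (i) the maximum image intensity,
#'   (ii) the mean image intensity and (iii) the intensity at the
#'   centrosome XY position.
#' @return An object of class `centrosome_z_model`.
#' @export
centrosome_z_model <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) == 4L, all(is.finite(coefficients)))
  structure(list(coefficients = coefficients), class = "centrosome_z_model")
}

#' Estimate the centrosome slice index
#'
#' Applies a linear regression on three image predictors (max
#' intensity, mean intensity, intensity at the XY position), rounds,
#' and clips to the valid slice range.  Without a model the central
#' slice is returned: 2D acquisitions are taken at half the cell
#' height, where the centrosome-bearing slice is expected.
#'
#' @param tubulin_cell [image2d()].
#' @param xy Integer 0-based `(x, y)` from [detect_centrosome_xy()].
#' @param model A [centrosome_z_model()] or `NULL` for the central-slice
#'   fallback.
#' @param n_slices Number of z slices in the target volume.
#' @return Integer 0-based slice index in `[0, n_slices - 1]`.
#' @export
estimate_centrosome_z <- function(tubulin_cell, xy, model = NULL,
                                  n_slices) {
  stopifnot(n_slices >= 1)
  if (is.null(model)) return(as.integer(floor(n_slices / 2)))
  stopifnot(inherits(model, "centrosome_z_model"))
  px <- tubulin_cell$pixels
  pred <- model$coefficients[1] +
    model$coefficients[2] * max(px) +
    model$coefficients[3] * mean(px) +
    model$coefficients[4] * px[xy[1] + 1L, xy[2] + 1L]
  as.integer(min(max(round(pred), 0), n_slices - 1L))
}

#' Assemble and validate a cell geometry
#'
#' Validates the containment invariants and relocates a centrosome that
#' falls outside the cytosol (inside the nucleus or outside the cell)
#' to the nearest cytosolic voxel, with a message.
#'
#' @param cell,nucleus [mask3d()] objects (nucleus inside cell).
#' @param centrosome Integer 0-based voxel triple `(x, y, z)`.
#' @return A [cell_geometry()].
#' @export
assemble_geometry <- function(cell, nucleus, centrosome) {
  stopifnot(inherits(cell, "mask3d"), inherits(nucleus, "mask3d"))
  if (any(nucleus$voxels & !cell$voxels))
    stop("nucleus mask is not contained in the cell mask")
  cytosol <- cell$voxels & !nucleus$voxels
  if (!any(cytosol)) stop("empty cytosol")
  centrosome <- as.integer(round(centrosome))
  d <- dim(cell$voxels)
  inside <- all(centrosome >= 0L) && all(centrosome < d) &&
    cytosol[centrosome[1] + 1L, centrosome[2] + 1L, centrosome[3] + 1L]
  if (!inside) {
    idx <- which(cytosol, arr.ind = TRUE) - 1L
    # anisotropic physical distance
    w <- c(cell$pixel_size_um, cell$pixel_size_um, cell$z_step_um)
    d2 <- (w[1] * (idx[, 1] - centrosome[1]))^2 +
          (w[2] * (idx[, 2] - centrosome[2]))^2 +
          (w[3] * (idx[, 3] - centrosome[3]))^2
    centrosome <- as.integer(idx[which.min(d2), ])
    message(sprintf("centrosome relocated to nearest cytosolic voxel (%d, %d, %d)",
                    centrosome[1], centrosome[2], centrosome[3]))
  }
  cell_geometry(cell, nucleus, centrosome)
}
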