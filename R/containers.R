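# Lightweight S3 containers shared by all modules.
#
# Conventions: pixel/voxel arrays are indexed [x, y] / [x, y, z] with x
# varying fastest (EBImage's layout); voxel indices are 0-based triples
# (x, y, z); continuous positions are in micrometres and map to voxels by
# floor(p / voxel_size).

#' 2D intensity image
#'
#' A single-channel 2D fluorescence image with its physical pixel size.
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities,
#'   indexed `[x, y]`.
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_um = 0.2) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("image2d: intensities must be finite and nonnegative")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "image2d")
}

#' 2D binary mask
#'
#' @param voxels Logical matrix indexed `[x, y]` (numeric input is
#'   coerced with `!= 0`).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return An object of class `mask2d`.
#' @export
mask2d <- function(voxels, pixel_size_um = 0.2) {
  voxels <- as.matrix(voxels)
  if (!is.logical(voxels)) voxels <- voxels != 0
  stopifnot(pixel_size_um > 0)
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um),
            class = "mask2d")
}

#' 3D binary mask
#'
#' @param voxels Logical 3D array indexed `[x, y, z]`.
#' @param pixel_size_um Lateral voxel size in micrometres.
#' @param z_step_um Axial slice spacing in micrometres (default 0.2).
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(voxels, pixel_size_um = 0.2, z_step_um = 0.2) {
  stopifnot(length(dim(voxels)) == 3L, pixel_size_um > 0, z_step_um > 0)
  if (!is.logical(voxels)) voxels <- voxels != 0
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "mask3d")
}

#' Number of pixels in a 2D mask
#' @param mask A [mask2d()].
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) sum(mask$voxels)

# per-slice pixel areas of a mask3d
slice_areas <- function(m3) apply(m3$voxels, 3L, sum)

#' 3D intensity volume
#'
#' @param voxels Numeric 3D array of nonnegative intensities.
#' @param voxel_size_um Lateral voxel size in micrometres.
#' @param z_step_um Axial slice spacing in micrometres.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size_um = 0.2, z_step_um = 0.2) {
  stopifnot(length(dim(voxels)) == 3L, voxel_size_um > 0, z_step_um > 0)
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("volume3d: intensities must be finite and nonnegative")
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 z_step_um = z_step_um),
            class = "volume3d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d px, %.3g um/px, range [%.3g, %.3g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.mask2d <- function(x, ...) {
  cat(sprintf("<mask2d %d x %d px, %.3g um/px, %d foreground px>\n",
              nrow(x$voxels), ncol(x$voxels), x$pixel_size_um,
              sum(x$voxels)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask3d %d x %d x %d, %.3g um/px, z-step %.3g um>\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d %d x %d x %d, total intensity %.4g>\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' Cell geometry: the conditioning context for microtubule growth
#'
#' Bundles the 3D cell and nuclear masks with the centrosome voxel.  The
#' centrosome must lie in the cytosol (cell AND NOT nucleus); see
#' [assemble_geometry()] for the validated constructor that relocates a
#' misplaced centrosome.
#'
#' @param cell,nucleus [mask3d()] objects of identical dimensions and
#'   voxel sizes, with `nucleus` contained in `cell`.
#' @param centrosome Integer 0-based voxel triple `(x, y, z)`.
#' @return An object of class `cell_geometry` with fields `cell`,
#'   `nucleus`, `cytosol` (logical array), `centrosome`,
#'   `voxel_size_um`, `z_step_um` and `height_um`.
#' @export
cell_geometry <- function(cell, nucleus, centrosome) {
  stopifnot(inherits(cell, "mask3d"), inherits(nucleus, "mask3d"))
  if (!identical(dim(cell$voxels), dim(nucleus$voxels)))
    stop("cell and nucleus masks must have identical dimensions")
  if (any(nucleus$voxels & !cell$voxels))
    stop("nucleus mask is not contained in the cell mask")
  centrosome <- as.integer(round(centrosome))
  stopifnot(length(centrosome) == 3L)
  d <- dim(cell$voxels)
  cytosol <- cell$voxels & !nucleus$voxels
  if (!any(cytosol)) stop("empty cytosol")
  if (any(centrosome < 0L) || any(centrosome >= d))
    stop("centrosome voxel outside the volume")
  if (!cytosol[centrosome[1] + 1L, centrosome[2] + 1L, centrosome[3] + 1L])
    stop("centrosome voxel is not cytosolic")
  structure(list(cell = cell, nucleus = nucleus, cytosol = cytosol,
                 centrosome = centrosome,
                 voxel_size_um = cell$pixel_size_um,
                 z_step_um = cell$z_step_um,
                 height_um = cell$z_step_um * d[3]),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  d <- dim(x$cell$voxels)
  cat(sprintf(
    "<cell_geometry %d x %d x %d, height %.2g um, centrosome (%d, %d, %d)>\n",
    d[1], d[2], d[3], x$height_um,
    x$centrosome[1], x$centrosome[2], x$centrosome[3]))
  invisible(x)
}

# continuous position (um) of a voxel centre
voxel_centre <- function(voxel, voxel_size_um, z_step_um) {
  c((voxel[1] + 0.5) * voxel_size_um,
    (voxel[2] + 0.5) * voxel_size_um,
    (voxel[3] + 0.5) * z_step_um)
}

# continuous positions (n x 3, um) -> 0-based voxel indices (n x 3)
position_to_voxel <- function(p, voxel_size_um, z_step_um) {
  cbind(floor(p[, 1] / voxel_size_um),
        floor(p[, 2] / voxel_size_um),
        floor(p[, 3] / z_step_um))
}
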