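# Imaging module: rasterization and the optical model (confocal PSF,
# single-microtubule intensity scaling, quantization, slicing).

#' Rasterize microtubules into a voxel volume
#'
#' Every polyline point increments the intensity of the voxel that
#' contains it by one, accumulating across microtubules, so the total
#' intensity equals the total number of rasterized points.
#'
#' @param mts List of `microtubule` objects (from
#'   [generate_distribution()]).
#' @param geom The [cell_geometry()] the microtubules were grown in;
#'   fixes the output volume's dimensions.
#' @return A [volume3d()] of the same dimensions as the geometry.
#' @export
render <- function(mts, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  d <- dim(geom$cell$voxels)
  counts <- numeric(prod(d))
  if (length(mts) > 0) {
    pts <- do.call(rbind, lapply(mts, `[[`, "points"))
    v <- position_to_voxel(pts, geom$voxel_size_um, geom$z_step_um)
    if (any(v < 0) || any(v[, 1] >= d[1] | v[, 2] >= d[2] | v[, 3] >= d[3]))
      stop("microtubule point outside the volume")
    idx <- 1 + v[, 1] + d[1] * (v[, 2] + d[2] * v[, 3])
    tab <- tabulate(idx, nbins = prod(d))
    counts <- counts + tab
  }
  volume3d(array(counts, d), geom$voxel_size_um, geom$z_step_um)
}

#' Parametric confocal point spread function
#'
#' Anisotropic 3D Gaussian approximation of the confocal PSF with
#' `sigma_lateral = 0.21 * lambda / NA` and
#' `sigma_axial = 0.75 * lambda * n_medium / NA^2` (immersion index
#' 1.515), sampled on the voxel grid, truncated at 3 sigma and
#' normalized to sum one.  Explicit sigma overrides (in voxels) take
#' precedence and allow matching any externally computed PSF width.
#'
#' @param voxel_size_um Lateral voxel size in micrometres.
#' @param z_step_um Axial slice spacing in micrometres.
#' @param numerical_aperture Objective NA (default 1.4).
#' @param emission_wavelength_nm Emission wavelength (default 565,
#'   Alexa555).
#' @param n_medium Immersion refractive index (default 1.515).
#' @param sigma_px Optional length-3 override `(sx, sy, sz)` in voxels.
#' @return An object of class `psf_model` with fields `kernel` (3D
#'   array summing to 1) and `params`.
#' @export
make_psf <- function(voxel_size_um = 0.2, z_step_um = 0.2,
                     numerical_aperture = 1.4,
                     emission_wavelength_nm = 565,
                     n_medium = 1.515, sigma_px = NULL) {
  stopifnot(voxel_size_um > 0, z_step_um > 0, numerical_aperture > 0,
            emission_wavelength_nm > 0)
  if (is.null(sigma_px)) {
    lambda_um <- emission_wavelength_nm / 1000
    s_lat <- 0.21 * lambda_um / numerical_aperture
    s_ax <- 0.75 * lambda_um * n_medium / numerical_aperture^2
    sigma_px <- c(s_lat / voxel_size_um, s_lat / voxel_size_um,
                  s_ax / z_step_um)
  }
  stopifnot(length(sigma_px) == 3L, all(sigma_px > 0))
  half <- pmax(1L, ceiling(3 * sigma_px))
  gx <- dnorm(seq(-half[1], half[1]), sd = sigma_px[1])
  gy <- dnorm(seq(-half[2], half[2]), sd = sigma_px[2])
  gz <- dnorm(seq(-half[3], half[3]), sd = sigma_px[3])
  k <- outer(outer(gx, gy), gz)
  k <- k / sum(k)
  structure(list(kernel = k,
                 params = list(voxel_size_um = voxel_size_um,
                               z_step_um = z_step_um,
                               numerical_aperture = numerical_aperture,
                               emission_wavelength_nm = emission_wavelength_nm,
                               n_medium = n_medium,
                               sigma_px = sigma_px)),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("<psf_model %d x %d x %d, sigma (%.2f, %.2f, %.2f) px>\n",
              d[1], d[2], d[3], x$params$sigma_px[1],
              x$params$sigma_px[2], x$params$sigma_px[3]))
  invisible(x)
}

#' Apply the optical model to a rendered volume
#'
#' Convolves the volume with the PSF kernel (same-size output,
#' zero-padded boundaries) and multiplies by the single-microtubule
#' intensity.  By default a kernel larger than the volume in any
#' dimension is an error; `pad = TRUE` zero-pads the volume by the
#' kernel half-width before convolving and crops back, which is the
#' appropriate treatment for thin stacks (a handful of z slices) whose
#' axial extent is below the 3-sigma support of the PSF.
#'
#' @param vol A [volume3d()].
#' @param psf A PSF model from [make_psf()].
#' @param single_mt_intensity Positive intensity scale per rasterized
#'   point (default 1).
#' @param pad Zero-pad the volume to accommodate a kernel larger than
#'   the stack (default `FALSE`).
#' @param quantize_8bit Clip to `[0, 255]` and round, emulating
#'   8-bit acquisition (default `FALSE`).
#' @return A [volume3d()].
#' @export
apply_optics <- function(vol, psf, single_mt_intensity = 1,
                         pad = FALSE, quantize_8bit = FALSE) {
  stopifnot(inherits(vol, "volume3d"), inherits(psf, "psf_model"),
            single_mt_intensity > 0)
  dv <- dim(vol$voxels); dk <- dim(psf$kernel)
  v <- vol$voxels
  if (any(dk > dv)) {
    if (!pad)
      stop("PSF kernel is larger than the volume; pad the volume ",
           "(pad = TRUE) or override sigma_px")
    h <- dk %/% 2
    big <- array(0, dv + 2 * h)
    big[h[1] + seq_len(dv[1]), h[2] + seq_len(dv[2]),
        h[3] + seq_len(dv[3])] <- v
    out <- array(conv3d_cpp(big, dim(big), psf$kernel, dk), dim(big))
    v <- out[h[1] + seq_len(dv[1]), h[2] + seq_len(dv[2]),
             h[3] + seq_len(dv[3])]
  } else {
    v <- array(conv3d_cpp(v, dv, psf$kernel, dk), dv)
  }
  v <- v * single_mt_intensity
  if (quantize_8bit) v <- round(pmin(pmax(v, 0), 255))
  v[v < 0] <- 0  # clip convolution round-off
  volume3d(v, vol$voxel_size_um, vol$z_step_um)
}

#' Estimate the fluorescence intensity of a single microtubule
#'
#' Heuristic estimator used to put synthetic images on a real image's
#' intensity scale: in the cell periphery (the outer 20% of the cell
#' mask by distance transform), microtubules are sparsest and rarely
#' overlap, so the mode of the nonzero intensity histogram there
#' approximates the brightness of one filament.  A known calibration
#' value can be passed through `override` and is returned unchanged.
#'
#' @param real [image2d()] of a single cell.
#' @param cell [mask2d()] cell mask.
#' @param override Optional known scalar intensity.
#' @param nbins Histogram bins for non-integer images (default 256).
#' @return Positive scalar intensity.
#' @export
estimate_single_mt_intensity <- function(real, cell, override = NULL,
                                         nbins = 256L) {
  if (!is.null(override)) {
    stopifnot(override > 0)
    return(override)
  }
  stopifnot(inherits(real, "image2d"), inherits(cell, "mask2d"))
  if (!any(cell$voxels)) stop("empty cell mask")
  d <- imageData(EBImage::distmap(ebimg(cell$voxels)))
  outer20 <- cell$voxels & d > 0 & d <= 0.2 * max(d)
  v <- real$pixels[outer20]
  v <- v[v > 0]
  if (length(v) == 0) stop("no nonzero pixels in the cell periphery")
  if (all(abs(v - round(v)) < 1e-9)) {
    tab <- table(v)
    as.numeric(names(tab)[which.max(tab)])
  } else {
    h <- hist(v, breaks = nbins, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}

#' Extract the central slice of a volume
#'
#' Returns the slice at half the cell height (0-based index
#' `floor(n_slices / 2)`), the plane at which 2D acquisitions are
#' taken.
#'
#' @param vol A [volume3d()] or [mask3d()].
#' @return An [image2d()] (or [mask2d()] for mask input).
#' @export
central_slice <- function(vol) {
  d <- dim(vol$voxels)
  stopifnot(length(d) == 3L, d[3] >= 1)
  k <- floor(d[3] / 2) + 1L
  if (inherits(vol, "mask3d"))
    mask2d(vol$voxels[, , k], vol$pixel_size_um)
  else
    image2d(vol$voxels[, , k], vol$voxel_size_um)
}

#' Write a volume or mask as a multi-page TIFF
#'
#' One page per z slice; intensities are stored as 32-bit float after
#' scaling by the volume maximum (recorded by callers that need to
#' invert it) or as 8-bit.
#'
#' @param vol [volume3d()] or [mask3d()].
#' @param path Output file.
#' @param bits 32 (float, values scaled to `[0, 1]` by `scale_max`) or
#'   8.
#' @param scale_max Intensity mapped to 1.0 (default the volume max).
#' @return `scale_max`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, bits = 32L, scale_max = NULL) {
  v <- vol$voxels * 1
  if (is.null(scale_max)) scale_max <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) pmin(pmax(t(v[, , k]) / scale_max, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(scale_max)
}

#' Read a 2D image from a TIFF file
#'
#' @param path TIFF file (first page is used).
#' @param pixel_size_um Physical pixel size to attach.
#' @return An [image2d()].
#' @export
read_image_tiff <- function(path, pixel_size_um = 0.2) {
  pg <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(pg)) == 3L) pg <- pg[, , 1]
  image2d(t(pg), pixel_size_um)
}
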