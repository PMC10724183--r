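#' PSF calibration for 3D Gaussian-approximation models
#'
#' Builds a calibration object describing how the Gaussian width of the point
#' spread function changes with depth, for either astigmatic (single plane) or
#' biplane imaging. The width model along each lateral axis is the truncated
#' cubic
#' \deqn{\sigma(z) = s_0 \sqrt{1 + u^2 + A u^3}, \quad u = (z - \gamma)/d,}
#' where \eqn{s_0} is the width (in pixels) at that axis' focal plane,
#' \eqn{\gamma} the focal offset, \eqn{d} the depth-of-focus parameter and
#' \eqn{A} a dimensionless cubic shape coefficient. Astigmatism is expressed by
#' giving the x and y axes opposite focal offsets; biplane imaging uses one
#' isotropic width model evaluated at the defocus relative to each detection
#' plane, with the photon signal (and background) split across planes.
#'
#' @param s0_x,s0_y in-focus widths in pixels (positive).
#' @param gamma_x,gamma_y focal offsets, in `axial_unit`.
#' @param d_x,d_y depth-of-focus parameters, in `axial_unit` (non-zero).
#' @param A_x,A_y cubic shape coefficients (dimensionless).
#' @param z_range closed axial interval (micrometres) on which the model is
#'   trusted; also the support of the axial position prior.
#' @param modality `"astigmatic"` (one detection plane) or `"biplane"`.
#' @param plane_offsets detection-plane depths in micrometres (length 1 or 2).
#' @param plane_fractions photon fraction detected in each plane; must sum
#'   to 1. Background photons are split by the same fractions.
#' @param axial_unit unit in which `gamma_*` and `d_*` are given: `"um"`
#'   (micrometres, the default) or `"px"` (100-nm pixel equivalents). Values
#'   are converted to micrometres internally, so `width_at_depth()` always
#'   takes z in micrometres.
#' @return An object of class `psf_calibration`.
#' @seealso [astigmatic_calibration()], [biplane_calibration()] for the presets
#'   used throughout the package's experiments.
#' @export
psf_calibration <- function(s0_x, gamma_x, d_x, A_x,
                            s0_y = s0_x, gamma_y = gamma_x, d_y = d_x, A_y = A_x,
                            z_range = c(-1.3, 1.3),
                            modality = c("astigmatic", "biplane"),
                            plane_offsets = 0,
                            plane_fractions = NULL,
                            axial_unit = c("um", "px")) {
  modality <- match.arg(modality)
  axial_unit <- match.arg(axial_unit)
  scale <- if (axial_unit == "px") 0.1 else 1  # 100 nm pixels
  stopifnot(s0_x > 0, s0_y > 0, d_x != 0, d_y != 0,
            length(z_range) == 2, z_range[1] < z_range[2])
  n_planes <- if (modality == "biplane") 2L else 1L
  if (length(plane_offsets) != n_planes)
    stop("'plane_offsets' must have length ", n_planes, " for ", modality, " imaging")
  if (is.null(plane_fractions)) plane_fractions <- rep(1 / n_planes, n_planes)
  if (length(plane_fractions) != n_planes || abs(sum(plane_fractions) - 1) > 1e-12)
    stop("'plane_fractions' must have length ", n_planes, " and sum to 1")
  structure(list(
    s0_x = s0_x, gamma_x = gamma_x * scale, d_x = d_x * scale, A_x = A_x,
    s0_y = s0_y, gamma_y = gamma_y * scale, d_y = d_y * scale, A_y = A_y,
    z_range = as.numeric(z_range), modality = modality,
    plane_offsets = as.numeric(plane_offsets),
    plane_fractions = as.numeric(plane_fractions),
    axial_unit = axial_unit
  ), class = "psf_calibration")
}

#' @export
print.psf_calibration <- function(x, ...) {
  cat("PSF calibration (", x$modality, ")\n", sep = "")
  cat(sprintf("  x axis: s0 = %.3g px, gamma = %.3g um, d = %.3g um, A = %.3g\n",
              x$s0_x, x$gamma_x, x$d_x, x$A_x))
  cat(sprintf("  y axis: s0 = %.3g px, gamma = %.3g um, d = %.3g um, A = %.3g\n",
              x$s0_y, x$gamma_y, x$d_y, x$A_y))
  cat(sprintf("  z range [%.2f, %.2f] um; planes at {%s} um, fractions {%s}\n",
              x$z_range[1], x$z_range[2],
              paste(x$plane_offsets, collapse = ", "),
              paste(x$plane_fractions, collapse = ", ")))
  invisible(x)
}

# flat numeric encoding consumed by the compiled core (axial values in um)
calib_vec <- function(calib) {
  c(calib$s0_x, calib$gamma_x, calib$d_x, calib$A_x,
    calib$s0_y, calib$gamma_y, calib$d_y, calib$A_y,
    calib$z_range, length(calib$plane_offsets),
    calib$plane_offsets[1],
    if (length(calib$plane_offsets) > 1) calib$plane_offsets[2] else 0,
    calib$plane_fractions[1],
    if (length(calib$plane_fractions) > 1) calib$plane_fractions[2] else 0)
}

#' Astigmatic PSF calibration preset
#'
#' The astigmatic calibration used by the package's two-emitter degeneracy
#' experiments: in-focus width 1.2 px, focal offsets of +2 and -2 (x and y),
#' depth-of-focus 3, no cubic term, usable depth range \[-1.3, 1.3\] um. The
#' focal offset and depth-of-focus are interpreted in micrometres; with this
#' choice the perpendicular "ghost" configuration of a close in-focus emitter
#' pair sits at a depth that grows with the pair separation and leaves the
#' usable depth range for well-separated pairs (see the methods vignette).
#'
#' @param sigma_psf in-focus width in pixels.
#' @param z_range usable depth range in micrometres.
#' @return A `psf_calibration` object.
#' @export
astigmatic_calibration <- function(sigma_psf = 1.2, z_range = c(-1.3, 1.3)) {
  psf_calibration(s0_x = sigma_psf, gamma_x = 2, d_x = 3, A_x = 0,
                  s0_y = sigma_psf, gamma_y = -2, d_y = 3, A_y = 0,
                  z_range = z_range, modality = "astigmatic",
                  plane_offsets = 0, axial_unit = "um")
}

#' Biplane PSF calibration preset
#'
#' Isotropic Gaussian width model `[1.70, -4.64, 8.34, 0.00]` (an experimentally
#' calibrated PSF), evaluated per detection plane at the defocus relative to
#' that plane. Axial parameters are in 100-nm pixel equivalents (gamma =
#' -464 nm, depth of focus 834 nm). Planes sit at +150 and -150 nm; photons and
#' background split evenly.
#'
#' @param plane_sep separation between the two detection planes in
#'   micrometres.
#' @param z_range usable depth range in micrometres.
#' @return A `psf_calibration` object.
#' @export
biplane_calibration <- function(plane_sep = 0.3, z_range = c(-1, 1)) {
  psf_calibration(s0_x = 1.70, gamma_x = -4.64, d_x = 8.34, A_x = 0,
                  z_range = z_range, modality = "biplane",
                  plane_offsets = c(plane_sep / 2, -plane_sep / 2),
                  axial_unit = "px")
}

#' Gaussian PSF width at a given depth
#'
#' Evaluates \eqn{\sigma(z) = s_0\sqrt{1 + u^2 + A u^3}} with
#' \eqn{u = (z-\gamma)/d}. At \eqn{z = \gamma} the width equals `s0`.
#'
#' @param calib a `psf_calibration`, or a numeric vector `c(s0, gamma, d, A)`
#'   with gamma and d in micrometres.
#' @param z axial positions in micrometres (vectorised).
#' @param axis `"x"` or `"y"` when `calib` is a `psf_calibration`.
#' @return widths in pixels.
#' @export
width_at_depth <- function(calib, z, axis = c("x", "y")) {
  if (inherits(calib, "psf_calibration")) {
    axis <- match.arg(axis)
    p <- if (axis == "x") c(calib$s0_x, calib$gamma_x, calib$d_x, calib$A_x)
         else              c(calib$s0_y, calib$gamma_y, calib$d_y, calib$A_y)
  } else {
    p <- as.numeric(calib)
    stopifnot(length(p) == 4)
  }
  w <- cpp_width_at_depth(as.numeric(z), p[1], p[2], p[3], p[4])
  if (any(w <= 0))
    stop("width model has non-positive radicand at z = ",
         paste(z[w <= 0], collapse = ", "), " (invalid calibration at that depth)")
  w
}

#' Pixel-integrated PSF photon fractions
#'
#' Expected fraction of an emitter's photons landing in each pixel of an
#' `nx` by `ny` grid, computed as the exact integral of the separable 2D
#' Gaussian over each pixel (difference of normal CDFs per axis). Pixel `i`
#' covers the half-open interval `[i, i+1)` in pixel units, starting at 0.
#' For biplane calibrations a list of two grids is returned, each scaled by
#' that plane's photon fraction.
#'
#' @param x,y emitter position in continuous pixel units.
#' @param z emitter depth in micrometres (must lie in `calib$z_range`).
#' @param calib a [psf_calibration()].
#' @param roi ROI size: single integer or `c(nx, ny)`.
#' @return A list of numeric matrices (one per plane) with dimension
#'   `c(nx, ny)`; rows index x, columns index y.
#' @export
pixel_fractions <- function(x, y, z, calib, roi) {
  stopifnot(inherits(calib, "psf_calibration"))
  roi <- as.integer(rep(roi, length.out = 2))
  stopifnot(all(roi > 0))
  if (z < calib$z_range[1] || z > calib$z_range[2])
    stop("z = ", z, " outside calibration z_range")
  cpp_pixel_fractions(x, y, z, calib_vec(calib), roi[1], roi[2])
}

#' Render a PSF z-scan
#'
#' Evaluates [pixel_fractions()] for a unit-intensity emitter at the ROI
#' centre over a grid of depths, one fraction grid (per plane) per depth.
#'
#' @param calib a [psf_calibration()].
#' @param z_grid depths in micrometres, all within `calib$z_range`.
#' @param roi ROI size, as in [pixel_fractions()].
#' @return A list with one element per depth, each the [pixel_fractions()]
#'   list of plane grids; attribute `z_grid` carries the depths.
#' @export
render_zscan <- function(calib, z_grid, roi) {
  roi <- as.integer(rep(roi, length.out = 2))
  out <- lapply(z_grid, function(z)
    pixel_fractions(roi[1] / 2, roi[2] / 2, z, calib, roi))
  attr(out, "z_grid") <- z_grid
  out
}

#' Write a z-scan (or any list of image grids) as a multi-page TIFF
#'
#' Needs the optional \pkg{tiff} package. Each page is normalised to the
#' global maximum so the stack is viewable; use the in-memory object for
#' quantitative work.
#'
#' @param zscan output of [render_zscan()].
#' @param path output file.
#' @param plane which plane to write for biplane scans.
#' @return `path`, invisibly.
#' @export
write_zscan_tiff <- function(zscan, path, plane = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF export")
  pages <- lapply(zscan, function(s) t(s[[plane]]))
  mx <- max(unlist(pages))
  pages <- lapply(pages, function(p) p / mx)
  tiff::writeTIFF(pages, path)
  invisible(path)
}
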