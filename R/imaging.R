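#' Emitter parameter set for one frame
#'
#' The parameter vector of the Poisson image model: per-emitter lateral
#' position (pixels), depth (micrometres) and intensity (photons), plus one
#' shared background level (photons per pixel, before any biplane split).
#'
#' @param x,y,z,I equal-length numeric vectors of emitter parameters
#'   (may be length 0 for a background-only frame).
#' @param b background photons per pixel (non-negative scalar).
#' @return An object of class `frame_params` with fields `x`, `y`, `z`, `I`,
#'   `b` and emitter count `k`.
#' @export
frame_params <- function(x = numeric(), y = numeric(), z = numeric(),
                         I = numeric(), b = 0) {
  k <- length(x)
  stopifnot(length(y) == k, length(z) == k, length(I) == k,
            all(I > 0), length(b) == 1, b >= 0)
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 I = as.numeric(I), b = as.numeric(b), k = k),
            class = "frame_params")
}

#' @export
print.frame_params <- function(x, ...) {
  cat("frame_params: k =", x$k, "emitters, background", x$b, "photons/px\n")
  if (x$k > 0)
    print(data.frame(x = x$x, y = x$y, z = x$z, I = x$I))
  invisible(x)
}

#' Photon-count frame
#'
#' A single-plane frame or an ordered biplane pair of integer photon-count
#' grids. Rows index x, columns index y; pixel `i` covers `[i, i+1)` pixel
#' units.
#'
#' @param planes an integer matrix, or a list of one or two integer matrices
#'   of identical dimension with non-negative entries.
#' @param pixel_size_nm physical pixel size used when reporting coordinates in
#'   nanometres.
#' @return An object of class `smlm_frame`.
#' @export
smlm_frame <- function(planes, pixel_size_nm = 100) {
  if (is.matrix(planes)) planes <- list(planes)
  stopifnot(length(planes) %in% 1:2)
  dims <- lapply(planes, dim)
  if (length(planes) == 2 && !identical(dims[[1]], dims[[2]]))
    stop("biplane planes must share one shape")
  planes <- lapply(planes, function(p) {
    if (any(p < 0)) stop("photon counts must be non-negative")
    storage.mode(p) <- "integer"
    p
  })
  structure(list(planes = planes, roi_shape = dims[[1]],
                 pixel_size_nm = pixel_size_nm),
            class = "smlm_frame")
}

#' @export
print.smlm_frame <- function(x, ...) {
  cat(sprintf("smlm_frame: %d plane(s) of %d x %d px (%g nm/px), total %d photons\n",
              length(x$planes), x$roi_shape[1], x$roi_shape[2],
              x$pixel_size_nm, sum(unlist(x$planes))))
  invisible(x)
}

#' Expected photon counts of the forward image model
#'
#' \deqn{\mu_i = \sum_{j=1}^{k} \theta_{I,j} \int_{A_i} H(\theta_{x,j},
#'   \theta_{y,j}, \theta_{z,j})\,dx\,dy + \theta_b,}
#' with the pixel integral taken from [pixel_fractions()]. For biplane
#' calibrations both signal and background are split by the plane fractions.
#'
#' @param params a [frame_params()].
#' @param calib a [psf_calibration()].
#' @param roi ROI size: single integer or `c(nx, ny)`.
#' @return A list of per-plane expected-count matrices.
#' @export
expected_counts <- function(params, calib, roi) {
  stopifnot(inherits(params, "frame_params"), inherits(calib, "psf_calibration"))
  roi <- as.integer(rep(roi, length.out = 2))
  cpp_expected_counts(list(x = params$x, y = params$y, z = params$z,
                           I = params$I, b = params$b),
                      calib_vec(calib), roi[1], roi[2])
}

#' Poisson log-likelihood of a frame
#'
#' \eqn{\log P(D \mid \theta, k) = \sum_i D_i \log\mu_i - \mu_i - \log D_i!},
#' summed over all pixels of all planes (pixels are independent, biplane
#' planes multiply).
#'
#' @param frame an [smlm_frame()] (or a single integer matrix).
#' @param mu expected counts: output of [expected_counts()] (or a single
#'   matrix).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(frame, mu) {
  if (is.matrix(frame)) frame <- smlm_frame(frame)
  if (is.matrix(mu)) mu <- list(mu)
  if (length(mu) != length(frame$planes)) stop("plane count mismatch")
  ll <- 0
  for (p in seq_along(mu)) {
    D <- frame$planes[[p]]
    m <- mu[[p]]
    if (!identical(dim(D), dim(m))) stop("shape mismatch between frame and mu")
    if (any(!is.finite(m)) || any(m < 0)) stop("invalid expected counts")
    if (any(m == 0 & D > 0)) return(-Inf)
    ok <- m > 0
    ll <- ll + sum(D[ok] * log(m[ok]) - m[ok] - lgamma(D[ok] + 1)) - sum(m[!ok])
  }
  ll
}

#' Convert camera ADU frames to photon counts
#'
#' `photons = max(0, round((raw - offset) / gain))`, applied elementwise.
#'
#' @param raw numeric matrix (or list of matrices) in camera units.
#' @param gain camera gain in ADU per photon (positive).
#' @param offset camera offset in ADU.
#' @param pixel_size_nm passed to [smlm_frame()].
#' @return An [smlm_frame()] with integer photon counts.
#' @export
adu_to_photons <- function(raw, gain, offset = 0, pixel_size_nm = 100) {
  if (gain <= 0) stop("gain must be positive")
  if (is.matrix(raw)) raw <- list(raw)
  planes <- lapply(raw, function(m) {
    ph <- round((m - offset) / gain)
    ph[ph < 0] <- 0
    storage.mode(ph) <- "integer"
    ph
  })
  smlm_frame(planes, pixel_size_nm = pixel_size_nm)
}

#' Read a TIFF stack as photon-count frames
#'
#' Thin wrapper over \pkg{tiff}; pages are read as matrices, converted with
#' [adu_to_photons()]. Biplane input may be supplied as two files (one per
#' plane) or one interleaved stack.
#'
#' @param path path to a TIFF stack (or length-2 vector of per-plane stacks).
#' @param gain,offset camera conversion, see [adu_to_photons()].
#' @param interleaved if `TRUE` and one path is given, odd pages are plane 1
#'   and even pages plane 2.
#' @return A list of [smlm_frame()] objects.
#' @export
read_frames_tiff <- function(path, gain = 1, offset = 0, interleaved = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF input")
  read_one <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    lapply(pages, t) # stored row = y; internal convention is row = x
  }
  if (length(path) == 2) {
    a <- read_one(path[1]); b <- read_one(path[2])
    if (length(a) != length(b)) stop("per-plane stacks differ in length")
    return(mapply(function(p1, p2) adu_to_photons(list(p1, p2), gain, offset),
                  a, b, SIMPLIFY = FALSE))
  }
  pages <- read_one(path)
  if (interleaved) {
    if (length(pages) %% 2 != 0) stop("interleaved stack needs an even page count")
    idx <- seq(1, length(pages), by = 2)
    return(lapply(idx, function(i)
      adu_to_photons(list(pages[[i]], pages[[i + 1]]), gain, offset)))
  }
  lapply(pages, function(p) adu_to_photons(p, gain, offset))
}

#' Write photon-count frames as a TIFF stack
#'
#' @param frames list of [smlm_frame()] objects with a shared geometry.
#' @param path output file; biplane frames are written interleaved
#'   (plane 1, plane 2, plane 1, ...).
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF output")
  pages <- list()
  for (f in frames)
    for (p in f$planes)
      pages[[length(pages) + 1]] <- t(p) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
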