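#' Emitter intensity prior
#'
#' A truncated-Gaussian intensity prior, optionally mixed with a trapezoidal
#' low-intensity tail that eases trans-dimensional moves (split emitters start
#' at roughly half the typical intensity, so some prior mass at low photon
#' counts helps the sampler propose and accept splits). The density is
#' \deqn{p(I) = (1-w)\,\mathcal{N}_{(0,c]}(I; m, \sigma) + w\,T(I),}
#' where \eqn{c = m + 3\sigma} is the hard upper cut (density is exactly zero
#' above it), and \eqn{T} is a trapezoid with knots `a <= b <= c2 <= d`:
#' linear ramp up on `[a, b]`, plateau on `[b, c2]`, ramp down on `[c2, d]`.
#'
#' @param mean Gaussian centre in photons.
#' @param width Gaussian standard deviation in photons.
#' @param tail `NULL` for a strictly Gaussian prior, otherwise a list with
#'   `knots` (length-4 numeric, the trapezoid breakpoints) and optionally
#'   `mass` (tail mass fraction, default 0.1).
#' @param upper_cut hard truncation point; defaults to `mean + 3 * width`.
#' @return An object of class `intensity_prior`.
#' @examples
#' p0 <- intensity_prior_preset("P0")
#' dintensity(c(1000, 2000, 2451), p0)  # zero beyond 2450
#' @export
intensity_prior <- function(mean, width, tail = NULL,
                            upper_cut = mean + 3 * width) {
  stopifnot(width > 0, upper_cut > 0)
  if (!is.null(tail)) {
    kn <- as.numeric(tail$knots)
    if (length(kn) != 4 || any(diff(kn) < 0) || kn[1] < 0)
      stop("tail$knots must be 4 nondecreasing non-negative breakpoints")
    if (kn[4] > upper_cut) stop("tail extends beyond the upper cut")
    if (kn[4] <= kn[1]) stop("tail has zero width")
    mass <- if (is.null(tail$mass)) 0.1 else tail$mass
    stopifnot(mass > 0, mass < 1)
    tail <- list(knots = kn, mass = mass)
  }
  structure(list(mean = mean, width = width, tail = tail,
                 upper_cut = upper_cut),
            class = "intensity_prior")
}

#' @export
print.intensity_prior <- function(x, ...) {
  cat(sprintf("intensity_prior: Gaussian(%g, %g) truncated to (0, %g]",
              x$mean, x$width, x$upper_cut))
  if (!is.null(x$tail))
    cat(sprintf(" + %g tail mass on trapezoid (%s)",
                x$tail$mass, paste(x$tail$knots, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Intensity prior presets
#'
#' `"P0"`--`"P3"`: Gaussians centred at 2000 photons with widths 150, 300,
#' 500 and 1000, truncated at `2000 + 3 * width`. P0 and P1 additionally carry
#' a low-intensity tail: uniform from 0 to 1500 photons, sloping down to zero
#' at 2000. `"biplane"`: Gaussian mean 1000, width 150, cut at 1450, with a
#' tail sloping up from 0 to 200 photons and uniform between 200 and 500.
#'
#' @param name one of `"P0"`, `"P1"`, `"P2"`, `"P3"`, `"biplane"`.
#' @param tail_mass tail mass fraction for the presets that have a tail.
#' @return An [intensity_prior()].
#' @export
intensity_prior_preset <- function(name = c("P0", "P1", "P2", "P3", "biplane"),
                                   tail_mass = 0.1) {
  name <- match.arg(name)
  down_tail <- list(knots = c(0, 0, 1500, 2000), mass = tail_mass)
  switch(name,
    P0 = intensity_prior(2000, 150, tail = down_tail),
    P1 = intensity_prior(2000, 300, tail = down_tail),
    P2 = intensity_prior(2000, 500),
    P3 = intensity_prior(2000, 1000),
    biplane = intensity_prior(1000, 150,
                              tail = list(knots = c(0, 200, 500, 500),
                                          mass = tail_mass)))
}

#' Intensity prior density
#'
#' @param I photon counts (vectorised).
#' @param prior an [intensity_prior()].
#' @return Normalised density values.
#' @export
dintensity <- function(I, prior) {
  stopifnot(inherits(prior, "intensity_prior"))
  pv <- prior_vec_intensity(prior)
  vapply(as.numeric(I), cpp_intensity_dens, numeric(1), prior = pv)
}

#' Sample from an intensity prior
#'
#' @param n number of draws.
#' @param prior an [intensity_prior()].
#' @return Numeric vector of intensities in photons.
#' @export
rintensity <- function(n, prior) {
  stopifnot(inherits(prior, "intensity_prior"))
  cpp_sample_intensity(n, prior_vec_intensity(prior))
}

# intensity-only slice of the flat prior encoding (rest zeroed)
prior_vec_intensity <- function(prior) {
  pv <- numeric(17)
  pv[9] <- 1
  pv[10] <- prior$mean; pv[11] <- prior$width; pv[12] <- prior$upper_cut
  if (!is.null(prior$tail)) {
    pv[13] <- prior$tail$mass
    pv[14:17] <- prior$tail$knots
  }
  pv
}

#' Prior set for one localization problem
#'
#' Combines the component priors the sampler needs: lateral position uniform
#' over the ROI expanded by a margin, axial position uniform over the
#' calibration's depth range, the intensity prior, a uniform background
#' interval, and a uniform emitter-count prior on `0..k_max`.
#'
#' @param calib a [psf_calibration()]; provides the axial support.
#' @param roi ROI size: single integer or `c(nx, ny)`.
#' @param intensity an [intensity_prior()].
#' @param margin_px lateral margin beyond the ROI in pixels (emitters just
#'   outside the ROI still contribute photons).
#' @param background uniform support of the background level, photons/pixel.
#' @param k_max largest emitter count considered.
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(calib, roi, intensity,
                      margin_px = 4, background = c(1, 40), k_max = 6) {
  stopifnot(inherits(calib, "psf_calibration"), inherits(intensity, "intensity_prior"),
            length(background) == 2, background[1] < background[2],
            background[1] > 0, k_max >= 0)
  roi <- as.integer(rep(roi, length.out = 2))
  structure(list(
    lateral_x = c(-margin_px, roi[1] + margin_px),
    lateral_y = c(-margin_px, roi[2] + margin_px),
    axial = calib$z_range,
    intensity = intensity,
    background = as.numeric(background),
    k_range = c(0L, as.integer(k_max)),
    roi = roi, margin_px = margin_px
  ), class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat("prior_set:\n")
  cat(sprintf("  lateral uniform x [%g, %g] px, y [%g, %g] px\n",
              x$lateral_x[1], x$lateral_x[2], x$lateral_y[1], x$lateral_y[2]))
  cat(sprintf("  axial uniform [%g, %g] um; background uniform [%g, %g] photons\n",
              x$axial[1], x$axial[2], x$background[1], x$background[2]))
  cat(sprintf("  emitter count uniform on %d..%d\n", x$k_range[1], x$k_range[2]))
  print(x$intensity)
  invisible(x)
}

# flat numeric encoding consumed by the compiled core
prior_vec <- function(priors) {
  stopifnot(inherits(priors, "prior_set"))
  ip <- priors$intensity
  c(priors$lateral_x, priors$lateral_y, priors$axial, priors$background,
    priors$k_range[2],
    ip$mean, ip$width, ip$upper_cut,
    if (is.null(ip$tail)) c(0, 0, 0, 0, 0) else c(ip$tail$mass, ip$tail$knots))
}

#' Log prior density of a parameter set
#'
#' Sum of the component log densities (positions, intensities, background,
#' count). Returns `-Inf` when any component is outside its support; this is
#' a value, not an error, so out-of-support proposals are rejected through a
#' zero prior ratio.
#'
#' @param params a [frame_params()].
#' @param priors a [prior_set()].
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors) {
  stopifnot(inherits(params, "frame_params"))
  cpp_state_lprior(list(x = params$x, y = params$y, z = params$z,
                        I = params$I, b = params$b),
                   prior_vec(priors))
}

#' Draw a parameter set from the priors
#'
#' @param priors a [prior_set()].
#' @param k emitter count (within the count prior's support).
#' @return A [frame_params()] with `log_prior(...) > -Inf`.
#' @export
sample_prior <- function(priors, k) {
  stopifnot(inherits(priors, "prior_set"))
  if (k < priors$k_range[1] || k > priors$k_range[2])
    stop("k = ", k, " outside the count prior support")
  s <- cpp_sample_prior_state(as.integer(k), prior_vec(priors))
  frame_params(s$x, s$y, s$z, s$I, s$b)
}
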