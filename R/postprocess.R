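#' MAP emitter count of a chain
#'
#' The mode of the emitter count over the post-burn-in RJMCMC samples, ties
#' broken toward the smaller count (parsimony).
#'
#' By default only emitters whose lateral position lies inside the ROI are
#' counted. The lateral prior deliberately extends a few pixels beyond the
#' ROI so the sampler can represent real neighbouring emitters whose signal
#' leaks into the frame; those margin emitters are nuisance structure, not
#' part of the frame's model, and excluding them from the count is what makes
#' the reported model match the question "how many emitters are in this
#' ROI". Set `within_roi = FALSE` to take the raw dimension of the sampled
#' state instead.
#'
#' @param chain an `smlm_chain` from [run_rjmcmc()], or an integer vector of
#'   k samples (counted as given).
#' @param within_roi count only emitters inside the ROI (default).
#' @return Integer MAP count.
#' @export
map_model <- function(chain, within_roi = TRUE) {
  if (inherits(chain, "smlm_chain")) {
    keep <- chain$phase != "burnin"
    k <- if (within_roi) inroi_counts(chain)[keep] else chain$k[keep]
  } else k <- chain
  if (length(k) == 0) stop("no post-burn-in samples")
  tab <- table(k)
  ks <- as.integer(names(tab))
  ks[tab == max(tab)][1] # names are sorted ascending: tie -> smaller k
}

# per-iteration number of emitters with lateral position inside the ROI
inroi_counts <- function(chain) {
  th <- chain$theta
  roi <- chain$roi_shape
  kmax <- ncol(th) / 4
  cnt <- integer(nrow(th))
  for (j in seq_len(kmax)) {
    x <- th[, 4 * j - 3]; y <- th[, 4 * j - 2]
    cnt <- cnt + (!is.na(x) & x >= 0 & x < roi[1] & y >= 0 & y < roi[2])
  }
  cnt
}

#' Fraction of frames whose MAP model matches the truth
#'
#' @param k_hat integer vector of per-frame MAP counts.
#' @param k_true true emitter count.
#' @return Fraction in `[0, 1]`.
#' @export
model_accuracy <- function(k_hat, k_true) {
  if (length(k_hat) == 0) stop("empty model list")
  mean(k_hat == k_true)
}

#' Histogram reconstruction from MCMC chains
#'
#' Pools the position samples of one or more chains and bins them into a 2D
#' histogram image, magnified relative to the camera pixel grid (one bin per
#' `1/magnification` pixel). This is the super-resolved reconstruction: the
#' posterior density of emitter positions, as sampled.
#'
#' @param chains an `smlm_chain` or a list of them (same ROI geometry).
#' @param plane `"xy"` or `"xz"` for 2D projections, or `"xyz"` for the full
#'   3D histogram (posterior modes that overlap laterally but sit at
#'   different depths stay separated there).
#' @param magnification bins per camera pixel along x and y.
#' @param z_bins number of z bins for the `"xz"` and `"xyz"` histograms.
#' @param phase which chain phase to pool; default `"mcmc"` uses the
#'   conditioned chains as the reconstructions do.
#' @return A matrix (or 3D array for `"xyz"`) of class `smlm_histogram` with
#'   bin-edge attributes `xbreaks`, `ybreaks` (and `zbreaks`); the total
#'   count equals the number of pooled samples inside the ROI and depth
#'   range.
#' @export
reconstruct <- function(chains, plane = c("xy", "xz", "xyz"),
                        magnification = 2.5, z_bins = 50, phase = "mcmc") {
  plane <- match.arg(plane)
  if (inherits(chains, "smlm_chain")) chains <- list(chains)
  if (length(chains) == 0) stop("no chains supplied")
  roi <- chains[[1]]$roi_shape
  for (ch in chains)
    if (!identical(ch$roi_shape, roi)) stop("chains come from different ROI geometries")
  zr <- chains[[1]]$priors$axial
  pts <- do.call(rbind, lapply(chains, chain_samples, phase = phase))
  xb <- seq(0, roi[1], by = 1 / magnification)
  zb3 <- seq(zr[1], zr[2], length.out = z_bins + 1)
  if (plane == "xy") {
    yb <- seq(0, roi[2], by = 1 / magnification)
    keep <- pts[, "x"] >= 0 & pts[, "x"] <= roi[1] &
            pts[, "y"] >= 0 & pts[, "y"] <= roi[2]
    h <- bin2d(pts[keep, "x"], pts[keep, "y"], xb, yb)
    zb <- NULL
  } else if (plane == "xz") {
    yb <- zb3
    keep <- pts[, "x"] >= 0 & pts[, "x"] <= roi[1] &
            pts[, "z"] >= zr[1] & pts[, "z"] <= zr[2]
    h <- bin2d(pts[keep, "x"], pts[keep, "z"], xb, yb)
    zb <- NULL
  } else {
    yb <- seq(0, roi[2], by = 1 / magnification)
    zb <- zb3
    keep <- pts[, "x"] >= 0 & pts[, "x"] <= roi[1] &
            pts[, "y"] >= 0 & pts[, "y"] <= roi[2] &
            pts[, "z"] >= zr[1] & pts[, "z"] <= zr[2]
    ix <- findInterval(pts[keep, "x"], xb, rightmost.closed = TRUE, all.inside = TRUE)
    iy <- findInterval(pts[keep, "y"], yb, rightmost.closed = TRUE, all.inside = TRUE)
    iz <- findInterval(pts[keep, "z"], zb, rightmost.closed = TRUE, all.inside = TRUE)
    dims <- c(length(xb) - 1, length(yb) - 1, length(zb) - 1)
    lin <- ix + (iy - 1) * dims[1] + (iz - 1) * dims[1] * dims[2]
    h <- array(tabulate(lin, nbins = prod(dims)), dims)
  }
  structure(h, xbreaks = xb, ybreaks = yb, zbreaks = zb, plane = plane,
            magnification = magnification,
            class = c("smlm_histogram", if (plane == "xyz") "array" else "matrix"))
}

bin2d <- function(x, y, xb, yb) {
  ix <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  h <- matrix(0, length(xb) - 1, length(yb) - 1)
  tab <- table(factor(ix, levels = seq_len(nrow(h))),
               factor(iy, levels = seq_len(ncol(h))))
  h[] <- as.numeric(tab)
  h
}

#' @export
plot.smlm_histogram <- function(x, main = NULL, ...) {
  xb <- attr(x, "xbreaks"); yb <- attr(x, "ybreaks")
  graphics::image(xb, yb, unclass(x)^0.5, col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x (px)",
                  ylab = if (attr(x, "plane") == "xy") "y (px)" else "z (um)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' k-means clustering of posterior position samples
#'
#' Clusters the pooled position point cloud; when emitters collapse (the
#' separation falls below what the PSF can resolve) the requested clusters
#' land on coincident centres, which is the collapse signature used by the
#' separability analyses.
#'
#' @param samples matrix with columns including `x`, `y` (and optionally
#'   `z`); e.g. [chain_samples()] output.
#' @param n_clusters number of clusters.
#' @param seed integer seed making the clustering deterministic.
#' @param columns which columns to cluster on.
#' @return The [stats::kmeans()] fit, with an extra element
#'   `center_separation`: the maximum pairwise distance between centres.
#' @export
cluster_modes <- function(samples, n_clusters, seed = 1, columns = c("x", "y")) {
  stopifnot(n_clusters >= 1, nrow(samples) > 0)
  m <- samples[, columns, drop = FALSE]
  if (nrow(unique(m)) < n_clusters) stop("fewer distinct samples than clusters")
  set.seed(seed)
  km <- stats::kmeans(m, centers = n_clusters, nstart = 10, iter.max = 50)
  d <- stats::dist(km$centers)
  km$center_separation <- if (n_clusters > 1) max(d) else 0
  km
}

#' Count modes of a histogram
#'
#' Operationalises "how many peaks can be distinguished": the histogram is
#' smoothed with a small box filter, and local maxima above a relative
#' threshold and at a minimum mutual distance are counted. Works on 2D
#' histogram images and on 3D (`"xyz"`) reconstructions; the 3D form is what
#' the separability analyses use, since degenerate modes that overlap
#' laterally remain separated in depth. All thresholds are recorded on the
#' result.
#'
#' @param h an `smlm_histogram` (2D matrix or 3D array), or a plain matrix.
#' @param threshold minimum peak height as a fraction of the global maximum.
#' @param min_separation minimum distance between counted peaks, in bins.
#' @param smooth half-width of the box smoothing filter in bins.
#' @return Integer mode count with attributes `peaks` (bin coordinates of the
#'   counted maxima, one row per peak, last column the height) and
#'   `settings`.
#' @export
count_modes <- function(h, threshold = 0.05, min_separation = 2, smooth = 1) {
  m <- unclass(h)
  attributes(m) <- list(dim = dim(m))
  if (length(m) == 0 || sum(m) == 0) stop("empty histogram")
  nd <- length(dim(m))
  if (!nd %in% 2:3) stop("histogram must be 2D or 3D")
  s <- box_smooth(m, smooth)
  cut <- threshold * max(s)
  cand <- which(s >= cut)
  dims <- dim(s)
  coord <- arrayInd(cand, dims)
  is_peak <- vapply(seq_along(cand), function(r) {
    ix <- coord[r, ]
    lo <- pmax(ix - 1, 1); hi <- pmin(ix + 1, dims)
    nb <- if (nd == 2) s[lo[1]:hi[1], lo[2]:hi[2]]
          else s[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    s[cand[r]] >= max(nb)
  }, logical(1))
  if (!any(is_peak)) return(structure(0L, peaks = NULL))
  peaks <- cbind(coord[is_peak, , drop = FALSE], s[cand[is_peak]])
  # greedy non-maximum suppression by height
  peaks <- peaks[order(-peaks[, nd + 1]), , drop = FALSE]
  kept <- peaks[0, , drop = FALSE]
  for (r in seq_len(nrow(peaks))) {
    p <- peaks[r, ]
    ok <- if (nrow(kept) == 0) TRUE else {
      d2 <- rowSums((kept[, 1:nd, drop = FALSE] -
                     rep(p[1:nd], each = nrow(kept)))^2)
      all(sqrt(d2) >= min_separation)
    }
    if (ok) kept <- rbind(kept, p)
  }
  structure(nrow(kept), peaks = kept,
            settings = list(threshold = threshold,
                            min_separation = min_separation, smooth = smooth))
}

# box-mean smoothing for 2D matrices and 3D arrays
box_smooth <- function(m, half_width) {
  if (half_width <= 0) return(m)
  dims <- dim(m)
  out <- array(0, dims)
  cnt <- array(0, dims)
  offs <- -half_width:half_width
  idx <- function(n, d) list(src = max(1, 1 + d):min(n, n + d),
                             dst = max(1, 1 - d):min(n, n - d))
  if (length(dims) == 2) {
    for (di in offs) for (dj in offs) {
      a <- idx(dims[1], di); b <- idx(dims[2], dj)
      out[a$dst, b$dst] <- out[a$dst, b$dst] + m[a$src, b$src]
      cnt[a$dst, b$dst] <- cnt[a$dst, b$dst] + 1
    }
  } else {
    for (di in offs) for (dj in offs) for (dk in offs) {
      a <- idx(dims[1], di); b <- idx(dims[2], dj); cc <- idx(dims[3], dk)
      out[a$dst, b$dst, cc$dst] <- out[a$dst, b$dst, cc$dst] + m[a$src, b$src, cc$src]
      cnt[a$dst, b$dst, cc$dst] <- cnt[a$dst, b$dst, cc$dst] + 1
    }
  }
  out / cnt
}

#' Pearson chi-square representativeness test
#'
#' Tests whether a fitted parameter set is representative of a frame:
#' statistic \eqn{\sum_i (D_i - \mu_i)^2/\mu_i} against the chi-square
#' quantile at confidence `1 - alpha` with `N_pixels - dim(theta)` degrees of
#' freedom (with `dim(theta) = 4k + 1`; configurable, since the dof convention
#' is a policy choice).
#'
#' @param frame an [smlm_frame()] or integer matrix.
#' @param mu expected counts under the tested parameter set.
#' @param alpha test level.
#' @param dof degrees of freedom; default `N_pixels - (4k + 1)` where k is
#'   taken from `n_param`.
#' @param n_param number of model parameters (`4k + 1`).
#' @return A list with `statistic`, `threshold`, `dof` and `representative`.
#' @export
chi_square_test <- function(frame, mu, alpha = 0.05, n_param = NULL, dof = NULL) {
  if (is.matrix(frame)) frame <- smlm_frame(frame)
  if (is.matrix(mu)) mu <- list(mu)
  np <- sum(vapply(mu, length, numeric(1)))
  stat <- 0
  for (p in seq_along(mu)) {
    m <- mu[[p]]
    if (any(m <= 0)) stop("expected counts must be positive for the chi-square test")
    stat <- stat + sum((frame$planes[[p]] - m)^2 / m)
  }
  if (is.null(dof)) {
    if (is.null(n_param)) n_param <- 0
    dof <- np - n_param
  }
  thr <- stats::qchisq(1 - alpha, dof)
  list(statistic = stat, threshold = thr, dof = dof,
       representative = stat <= thr)
}

#' Mode-confusion probability of a degenerate mode pair
#'
#' Simulates Poisson frames from each of two candidate parameter sets and
#' records how often the *other* one attains the higher likelihood; the
#' average over both generating hypotheses is the probability that a
#' likelihood comparison selects the wrong mode. Values near 0.5 mean the
#' modes are statistically indistinguishable.
#'
#' @param mode_a,mode_b [frame_params()] of the two modes.
#' @param calib a [psf_calibration()].
#' @param roi ROI size.
#' @param n_sim simulated frames per hypothesis.
#' @param seed integer seed.
#' @return Error probability in `[0, ~0.5]`.
#' @export
mode_error_probability <- function(mode_a, mode_b, calib, roi, n_sim = 10000,
                                   seed = 1) {
  stopifnot(n_sim >= 1)
  mu_a <- unlist(expected_counts(mode_a, calib, roi))
  mu_b <- unlist(expected_counts(mode_b, calib, roi))
  set.seed(seed)
  e_a <- cpp_mode_confusion(mu_a, mu_b, as.integer(n_sim))
  e_b <- cpp_mode_confusion(mu_b, mu_a, as.integer(n_sim))
  (e_a + e_b) / 2
}

#' KL-matched perpendicular (ghost) mode of an in-focus emitter pair
#'
#' For two equal-intensity emitters separated in the focal plane, astigmatic
#' imaging admits a degenerate counterpart: a pair perpendicular to the true
#' separation axis at a different depth. This function finds that counterpart
#' by minimising the Kullback-Leibler divergence from the true expected image
#' to a perpendicular-pair image over (separation, depth, intensity,
#' background) - i.e. the alternate likelihood optimum.
#'
#' @param true_params a symmetric in-focus two-emitter [frame_params()].
#' @param calib a [psf_calibration()].
#' @param roi ROI size.
#' @param z_start depth starting points for the multi-start optimisation
#'   (micrometres); defaults to a grid spanning the calibration range.
#' @param exclude_focus half-width (micrometres) of the depth band around the
#'   true depth to exclude, so the optimiser finds the *other* mode rather
#'   than the (rotationally trivial) in-focus solution.
#' @return A list with `params` (the alternate-mode [frame_params()]),
#'   `kl` (KL divergence in photons), `separation_px` and `z_um`.
#' @export
find_alternate_mode <- function(true_params, calib, roi, z_start = NULL,
                                exclude_focus = 0.1) {
  stopifnot(true_params$k == 2)
  roi <- as.integer(rep(roi, length.out = 2))
  mu_t <- unlist(expected_counts(true_params, calib, roi))
  cx <- mean(true_params$x); cy <- mean(true_params$y)
  z0 <- mean(true_params$z)
  # perpendicular axis to the true separation
  dx <- diff(true_params$x); dy <- diff(true_params$y)
  nrm <- sqrt(dx^2 + dy^2)
  ux <- -dy / nrm; uy <- dx / nrm
  zr <- calib$z_range
  if (is.null(z_start)) z_start <- seq(zr[1] * 0.95, zr[2] * 0.95, length.out = 11)
  z_start <- z_start[abs(z_start - z0) > exclude_focus]
  obj <- function(p) {
    s <- abs(p[1]); z <- p[2]; I <- exp(p[3]); b <- exp(p[4])
    if (z < zr[1] || z > zr[2] || abs(z - z0) <= exclude_focus) return(1e12)
    alt <- frame_params(c(cx - ux * s / 2, cx + ux * s / 2),
                        c(cy - uy * s / 2, cy + uy * s / 2),
                        c(z, z), c(I, I), b)
    mu_a <- unlist(expected_counts(alt, calib, roi))
    sum(mu_t * log(mu_t / mu_a) - mu_t + mu_a)
  }
  best <- NULL
  s0 <- nrm
  for (zs in z_start) {
    o <- stats::optim(c(s0, zs, log(mean(true_params$I)), log(true_params$b)),
                      obj, control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s <- abs(best$par[1]); z <- best$par[2]
  I <- exp(best$par[3]); b <- exp(best$par[4])
  params <- frame_params(c(cx - ux * s / 2, cx + ux * s / 2),
                         c(cy - uy * s / 2, cy + uy * s / 2),
                         c(z, z), c(I, I), b)
  list(params = params, kl = best$value, separation_px = s, z_um = z)
}

#' Posterior summary across the frames of an experiment
#'
#' @param fits list of [fit_emitters()] results.
#' @param k_true optional true emitter count, enabling the accuracy field.
#' @return An object of class `posterior_summary` with the per-frame MAP
#'   counts, their histogram, the pooled MCMC samples and (optionally) the
#'   model accuracy.
#' @export
posterior_summary <- function(fits, k_true = NULL) {
  map_k <- vapply(fits, function(f) f$map_k, integer(1))
  samples <- do.call(rbind, lapply(fits, function(f) chain_samples(f$mcmc, "mcmc")))
  structure(list(
    map_k = map_k,
    k_histogram = table(map_k),
    samples = samples,
    accuracy = if (!is.null(k_true)) model_accuracy(map_k, k_true) else NULL,
    k_true = k_true
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary over", length(x$map_k), "frames\n")
  cat("  MAP k histogram:\n")
  print(x$k_histogram)
  if (!is.null(x$accuracy))
    cat(sprintf("  model accuracy vs k = %d: %.3f\n", x$k_true, x$accuracy))
  invisible(x)
}

#' Export pooled localizations as a table
#'
#' One row per MCMC position sample, in pixels and nanometres.
#'
#' @param fits list of [fit_emitters()] results.
#' @param pixel_size_nm physical pixel size.
#' @param file optional CSV path; when given the table is also written.
#' @return A data frame with columns `frame`, `x_px`, `y_px`, `z_um`,
#'   `x_nm`, `y_nm`, `z_nm`, `I`, `map_k`.
#' @export
localization_table <- function(fits, pixel_size_nm = 100, file = NULL) {
  rows <- lapply(seq_along(fits), function(i) {
    s <- chain_samples(fits[[i]]$mcmc, "mcmc")
    if (nrow(s) == 0) return(NULL)
    data.frame(frame = i, x_px = s[, "x"], y_px = s[, "y"], z_um = s[, "z"],
               x_nm = s[, "x"] * pixel_size_nm, y_nm = s[, "y"] * pixel_size_nm,
               z_nm = s[, "z"] * 1000, I = s[, "I"], map_k = fits[[i]]$map_k)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}
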