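#' Simulate a photon-count frame
#'
#' Independent Poisson draw per pixel with mean from [expected_counts()].
#' Biplane calibrations produce an ordered pair of planes with signal and
#' background split by the plane fractions.
#'
#' @param params a [frame_params()] (the ground truth).
#' @param calib a [psf_calibration()].
#' @param roi ROI size: single integer or `c(nx, ny)`.
#' @param seed integer seed; fixed seed gives an identical frame.
#' @return An [smlm_frame()].
#' @export
simulate_frame <- function(params, calib, roi, seed = NULL) {
  mu <- expected_counts(params, calib, roi)
  if (!is.null(seed)) set.seed(seed)
  planes <- lapply(mu, function(m) {
    d <- m
    d[] <- stats::rpois(length(m), m)
    storage.mode(d) <- "integer"
    d
  })
  smlm_frame(planes)
}

#' Experiment design presets
#'
#' Builds the synthetic designs the package's degeneracy studies use:
#'
#' * `"astigmatic"` - astigmatic two-emitter separability: 20 x 20 ROI,
#'   in-focus width 1.2 px, both emitters in focus with intensity 2000
#'   photons, background 20, centre of mass at the ROI centre, separations
#'   `{3, 2.5, 2, 1.5, 1.25, 1, 0.75}` times the in-focus width along x,
#'   100 frames per separation, intensity prior P0 by default (set `prior`
#'   to `"P1"`..`"P3"` for the prior-width study, which re-analyses the
#'   same frames under a different intensity prior).
#' * `"biplane"` - biplane two-emitter separability: 30 x 30 ROI, planes at
#'   +/-150 nm, depth range [-1, 1] um, photons and background split evenly,
#'   biplane intensity prior (mean 1000, width 150, per plane).
#' * `"convergence"` - single-emitter model convergence: one emitter at the
#'   ROI centre with a random sub-pixel displacement and intensity drawn
#'   from the intensity prior, 100 frames.
#'
#' @param preset one of `"astigmatic"`, `"biplane"`, `"convergence"`.
#' @param n_frames frames per separation (or in total for `"convergence"`).
#' @param separations separation grid in multiples of the in-focus PSF width.
#' @param beta_deg orientation of the emitter pair (0 = along x).
#' @param prior intensity prior preset name.
#' @param intensity,background emitter intensity and background (photons).
#' @param seed master seed; per-frame seeds are derived by a counter so any
#'   frame is reproducible in isolation.
#' @return An object of class `experiment_design`.
#' @export
make_design <- function(preset = c("astigmatic", "biplane", "convergence"),
                        n_frames = 100,
                        separations = c(3, 2.5, 2, 1.5, 1.25, 1, 0.75),
                        beta_deg = 0, prior = NULL,
                        intensity = 2000, background = 20, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "astigmatic") {
    calib <- astigmatic_calibration()
    roi <- c(20L, 20L)
    if (is.null(prior)) prior <- "P0"
  } else if (preset == "biplane") {
    calib <- biplane_calibration()
    roi <- c(30L, 30L)
    prior <- "biplane"
  } else {
    calib <- astigmatic_calibration()
    roi <- c(20L, 20L)
    if (is.null(prior)) prior <- "P0"
    separations <- numeric(0)
  }
  structure(list(preset = preset, calib = calib, roi = roi,
                 n_frames = n_frames, separations = separations,
                 beta_deg = beta_deg, prior_name = prior,
                 intensity = intensity, background = background, seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design '%s': %d frames, ROI %d x %d, %s PSF\n",
              x$preset, x$n_frames, x$roi[1], x$roi[2], x$calib$modality))
  if (length(x$separations))
    cat("  separations (x sigma_PSF):", paste(x$separations, collapse = ", "), "\n")
  cat(sprintf("  I = %g photons, b = %g, prior %s, seed %d\n",
              x$intensity, x$background, x$prior_name, x$seed))
  invisible(x)
}

#' Intensity prior of a design, on the total-intensity scale
#'
#' The intensity parameter of the model is the emitter's total photon count.
#' Presets quoted on the per-plane scale (the biplane prior: Gaussian mean
#' 1000, width 150, with its tail) are rescaled by the number of planes so
#' that the prior applies to the same quantity the model parametrises.
#'
#' @param design an [make_design()] result.
#' @return An [intensity_prior()].
#' @export
design_intensity_prior <- function(design) {
  ip <- intensity_prior_preset(design$prior_name)
  n_planes <- length(design$calib$plane_offsets)
  if (n_planes > 1) ip <- rescale_intensity_prior(ip, n_planes)
  ip
}

rescale_intensity_prior <- function(prior, factor) {
  intensity_prior(prior$mean * factor, prior$width * factor,
                  tail = if (is.null(prior$tail)) NULL else
                    list(knots = prior$tail$knots * factor,
                         mass = prior$tail$mass),
                  upper_cut = prior$upper_cut * factor)
}

#' Ground-truth parameters of a design at one separation
#'
#' Two emitters `m * s0` pixels apart (centre of mass at the ROI centre)
#' under angle `beta_deg`, in focus; or, for the convergence design, one
#' centred emitter whose sub-pixel offset and intensity are drawn from the
#' priors.
#'
#' @param design an [make_design()] result.
#' @param separation separation in multiples of the in-focus PSF width
#'   (ignored for the convergence preset).
#' @param frame_id frame index; seeds the random elements of the
#'   convergence truth.
#' @return A [frame_params()].
#' @export
design_truth <- function(design, separation = NULL, frame_id = 1) {
  cx <- design$roi[1] / 2; cy <- design$roi[2] / 2
  if (design$preset == "convergence") {
    set.seed(design$seed * 100003L + frame_id)
    ip <- design_intensity_prior(design)
    # emitter brightness follows the Gaussian component of the intensity
    # prior; the low-intensity tail is a sampler device, not a brightness
    # model, and tail-bright emitters of a few hundred photons would be
    # undetectable by construction
    ip_core <- intensity_prior(ip$mean, ip$width, upper_cut = ip$upper_cut)
    frame_params(x = cx + stats::runif(1, -0.5, 0.5),
                 y = cy + stats::runif(1, -0.5, 0.5),
                 z = 0,
                 I = rintensity(1, ip_core),
                 b = design$background)
  } else {
    stopifnot(!is.null(separation))
    d_px <- separation * design$calib$s0_x
    a <- beta_rad <- design$beta_deg * pi / 180
    ux <- cos(a); uy <- sin(a)
    frame_params(x = cx + c(-1, 1) * ux * d_px / 2,
                 y = cy + c(-1, 1) * uy * d_px / 2,
                 z = c(0, 0),
                 I = rep(design$intensity, 2),
                 b = design$background)
  }
}

#' Simulate the frames of a design
#'
#' @param design an [make_design()] result.
#' @param separation separation in sigma_PSF units (`NULL` for the
#'   convergence preset).
#' @return A list with `frames` (list of [smlm_frame()]) and `truths`
#'   (list of [frame_params()]).
#' @export
simulate_frames <- function(design, separation = NULL) {
  lapply_named <- function(i) {
    truth <- design_truth(design, separation, frame_id = i)
    sep_key <- if (is.null(separation)) 0 else round(separation * 1000)
    frame_seed <- (design$seed * 1000003L + sep_key * 1009L + i) %% .Machine$integer.max
    list(truth = truth,
         frame = simulate_frame(truth, design$calib, design$roi, seed = frame_seed))
  }
  out <- lapply(seq_len(design$n_frames), lapply_named)
  list(frames = lapply(out, `[[`, "frame"),
       truths = lapply(out, `[[`, "truth"))
}

#' Run a full experiment: simulate, fit, summarise
#'
#' Executes the pipeline for every frame of a design (at one separation, or
#' in total for the convergence preset): simulate the frame, run RJMCMC,
#' select the MAP model, run the conditioned MCMC, and pool the results.
#'
#' @param design an [make_design()] result.
#' @param separation separation in sigma_PSF units (`NULL` for convergence).
#' @param n_rjmcmc,n_burn,n_mcmc per-frame iteration budget.
#' @param n_chains independent RJMCMC chains per frame; defaults to 4 for
#'   astigmatic designs (whose degenerate decompositions demand replication,
#'   see the methods vignette) and 2 for biplane designs.
#' @param priors optional [prior_set()] override; defaults to the design's
#'   prior preset with the standard supports.
#' @param verbose print per-frame progress.
#' @return A list of class `emitter_experiment` with `fits`, `summary`
#'   (a [posterior_summary()] with `k_true = 2` or `1`), `truths` and the
#'   design metadata.
#' @export
run_experiment <- function(design, separation = NULL,
                           n_rjmcmc = 30000, n_burn = 10000, n_mcmc = 5000,
                           n_chains = NULL, priors = NULL, verbose = FALSE) {
  sim <- simulate_frames(design, separation)
  if (is.null(priors))
    priors <- prior_set(design$calib, design$roi, design_intensity_prior(design))
  if (is.null(n_chains))
    n_chains <- if (design$calib$modality == "biplane") 2L else 4L
  k_true <- if (design$preset == "convergence") 1L else 2L
  fits <- vector("list", design$n_frames)
  for (i in seq_len(design$n_frames)) {
    sep_key <- if (is.null(separation)) 0 else round(separation * 1000)
    fit_seed <- (design$seed * 2000003L + sep_key * 1013L + i) %% .Machine$integer.max
    fits[[i]] <- fit_emitters(sim$frames[[i]], design$calib, priors,
                              n_rjmcmc = n_rjmcmc, n_burn = n_burn,
                              n_mcmc = n_mcmc, n_chains = n_chains,
                              seed = fit_seed, keep_chains = FALSE)
    if (verbose)
      message(sprintf("frame %d/%d: MAP k = %d", i, design$n_frames,
                      fits[[i]]$map_k))
  }
  structure(list(fits = fits, truths = sim$truths,
                 summary = posterior_summary(fits, k_true = k_true),
                 design = design, separation = separation),
            class = "emitter_experiment")
}

#' Separability analysis of an experiment
#'
#' The summary the two-emitter degeneracy studies report per separation: the
#' model accuracy, the mode count of the pooled 3D posterior reconstruction,
#' and the k-means collapse diagnostic. Counting modes in 3D matters: the
#' degenerate (perpendicular, deeper) mode overlaps the true pair laterally
#' at small separations, but stays separated in depth.
#'
#' The mode analysis pools the model-conditional samples of the
#' trans-dimensional RJMCMC chains rather than the conditioned MCMC chains:
#' the fixed-dimension chains stay in whichever degenerate basin they start
#' in, so at small frame counts their pooled mode weights are noisy, while
#' the RJMCMC chains cross between the basins.
#'
#' @param experiment an [run_experiment()] result.
#' @param magnification lateral bins per pixel of the analysis histogram.
#' @param z_bins depth bins of the analysis histogram.
#' @param threshold,min_separation,smooth passed to [count_modes()];
#'   defaults are the settings used throughout the package's separability
#'   analyses.
#' @return A list with `accuracy`, `n_modes`, the [cluster_modes()] fit of
#'   the pooled XY samples (`kmeans2`), its `center_separation_px`, and the
#'   pooled samples.
#' @export
experiment_separability <- function(experiment, magnification = 5, z_bins = 20,
                                    threshold = 0.05, min_separation = 5,
                                    smooth = 1) {
  samples <- do.call(rbind, lapply(experiment$fits, `[[`, "rj_samples"))
  roi <- experiment$design$roi
  zr <- experiment$design$calib$z_range
  xb <- seq(0, roi[1], by = 1 / magnification)
  yb <- seq(0, roi[2], by = 1 / magnification)
  zb <- seq(zr[1], zr[2], length.out = z_bins + 1)
  keep <- samples[, "z"] >= zr[1] & samples[, "z"] <= zr[2]
  ix <- findInterval(samples[keep, "x"], xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(samples[keep, "y"], yb, rightmost.closed = TRUE, all.inside = TRUE)
  iz <- findInterval(samples[keep, "z"], zb, rightmost.closed = TRUE, all.inside = TRUE)
  dims <- c(length(xb) - 1, length(yb) - 1, z_bins)
  h3 <- array(tabulate(ix + (iy - 1) * dims[1] + (iz - 1) * dims[1] * dims[2],
                       nbins = prod(dims)), dims)
  n <- count_modes(h3, threshold = threshold,
                   min_separation = min_separation, smooth = smooth)
  km <- cluster_modes(samples, 2, seed = 1)
  list(accuracy = experiment$summary$accuracy,
       n_modes = as.integer(n),
       kmeans2 = km,
       center_separation_px = km$center_separation,
       samples = samples)
}

#' @export
print.emitter_experiment <- function(x, ...) {
  cat(sprintf("emitter_experiment '%s'%s\n", x$design$preset,
              if (!is.null(x$separation))
                sprintf(" at %.2f sigma_PSF", x$separation) else ""))
  print(x$summary)
  invisible(x)
}
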