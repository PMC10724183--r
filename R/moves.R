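#' Move-selection schedule
#'
#' Probabilities of the nine sampler moves
#' (single, group, background, split, merge, g-split, g-merge, birth, death)
#' in each of the three phases. The defaults are the schedules used throughout
#' the package's experiments: burn-in emphasises model-space moves, the
#' post-burn-in phase keeps reduced model mixing, and the conditioned MCMC
#' phase uses parameter-space moves only.
#'
#' @param burnin,post,mcmc length-9 probability vectors summing to 1. The
#'   `mcmc` row must put zero probability on all model-space moves
#'   (split/merge/g-split/g-merge/birth/death).
#' @return A 3 x 9 matrix of class `move_schedule` with labelled rows and
#'   columns.
#' @export
move_schedule <- function(
    burnin = c(1/5, 1/5, 1/5, 1/15, 1/15, 1/15, 1/15, 1/15, 1/15),
    post   = c(1/4, 1/4, 1/4, 0, 0, 3/32, 3/32, 1/32, 1/32),
    mcmc   = c(2/5, 2/5, 1/5, 0, 0, 0, 0, 0, 0)) {
  m <- rbind(burnin = burnin, post = post, mcmc = mcmc)
  colnames(m) <- move_names()
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
    stop("each phase's move probabilities must be non-negative and sum to 1")
  if (any(m["mcmc", 4:9] != 0))
    stop("the mcmc phase must not select model-space moves")
  structure(m, class = c("move_schedule", "matrix"))
}

move_names <- function() {
  c("single", "group", "background", "split", "merge",
    "g-split", "g-merge", "birth", "death")
}

#' Random-walk jump sizes
#'
#' Standard deviations of the Gaussian random-walk proposals, plus the scales
#' of the split displacement draw. Defaults are the settings used in the
#' package's experiments: lateral 0.1 px, axial 0.08 um, intensity 15 photons,
#' background 1 photon. The split displacement scales (1 px lateral, 0.5 um
#' axial) set how far apart a freshly split pair starts.
#'
#' @param sigma_x,sigma_y lateral steps in pixels.
#' @param sigma_z axial step in micrometres.
#' @param sigma_I intensity step in photons.
#' @param sigma_b background step in photons.
#' @param split_xy,split_z split displacement scales (pixels, micrometres).
#' @param gmerge_xy,gmerge_I scales of the g-merge replacement proposal: the
#'   merged emitter is drawn around the pair's lateral midpoint
#'   (sd `gmerge_xy` pixels), with depth uniform over the axial range and
#'   intensity around the pair's total (sd `gmerge_I` photons).
#' @return An object of class `jump_sizes`.
#' @export
jump_sizes <- function(sigma_x = 0.1, sigma_y = 0.1, sigma_z = 0.08,
                       sigma_I = 15, sigma_b = 1,
                       split_xy = 1, split_z = 0.5,
                       gmerge_xy = 0.5, gmerge_I = 50) {
  v <- c(sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
         sigma_I = sigma_I, sigma_b = sigma_b,
         split_xy = split_xy, split_z = split_z,
         gmerge_xy = gmerge_xy, gmerge_I = gmerge_I)
  if (any(v[1:7] <= 0) || gmerge_I <= 0) stop("jump sizes must be positive")
  if (gmerge_xy < 0) stop("gmerge_xy must be >= 0 (0 selects prior-based g-moves)")
  structure(as.list(v), class = "jump_sizes")
}

jumps_vec <- function(jumps) unlist(jumps, use.names = FALSE)

as_state <- function(params) {
  list(x = params$x, y = params$y, z = params$z, I = params$I, b = params$b)
}

state_to_params <- function(s) frame_params(s$x, s$y, s$z, s$I, s$b)

propose_impl <- function(params, move_id, priors, jumps, calib, sched_row) {
  stopifnot(inherits(params, "frame_params"))
  res <- cpp_propose(as_state(params), as.integer(move_id),
                     calib_vec(calib), prior_vec(priors),
                     jumps_vec(jumps), sched_row)
  list(params = state_to_params(res$state),
       log_q_ratio = res$log_q_ratio,
       log_jacobian = res$log_jacobian,
       log_move_ratio = res$log_move_ratio,
       valid = res$valid)
}

#' Propose a parameter-space move
#'
#' `single` perturbs one uniformly chosen emitter's (x, y, z, I) by
#' independent Gaussian steps; `group` rigidly translates all emitters of one
#' overlap group (connected components under lateral distance < 4 PSF widths)
#' by a shared Gaussian step; `background` perturbs the background level.
#' All three leave the emitter count unchanged. The proposals are symmetric
#' random walks, so the returned `log_q_ratio` is zero except for the group
#' move, where a change in the number of overlap groups makes the group
#' choice asymmetric.
#'
#' @param params current [frame_params()].
#' @param kind `"single"`, `"group"` or `"background"`.
#' @param jumps a [jump_sizes()].
#' @param priors a [prior_set()].
#' @param calib a [psf_calibration()] (sets the overlap radius of the group
#'   move).
#' @return A list with `params` (the proposal), `log_q_ratio`,
#'   `log_jacobian` (always 0 here) and `valid` (`FALSE` is an auto-rejected
#'   no-op, e.g. a single move with no emitters).
#' @export
propose_parameter_move <- function(params, kind = c("single", "group", "background"),
                                   jumps, priors, calib) {
  kind <- match.arg(kind)
  id <- match(kind, move_names())
  propose_impl(params, id, priors, jumps, calib, default_row())
}

#' Propose a trans-dimensional split/merge move
#'
#' `split` replaces one emitter by two, conserving total intensity and the
#' intensity-weighted centroid: with intensity fraction `f ~ U(0,1)` and a
#' Gaussian displacement, the children are placed at
#' `pos + (1-f) * delta` and `pos - f * delta` with intensities `f I` and
#' `(1-f) I`; the absolute Jacobian of this transform is the parent intensity.
#' `merge` is its exact inverse applied to a uniformly chosen emitter and its
#' nearest neighbour. `g-split`/`g-merge` instead draw the replacement
#' emitters directly from the prior (no centroid constraint), which lets the
#' sampler jump between distant posterior modes.
#'
#' The returned `log_q_ratio` is the log of the reverse-to-forward proposal
#' density ratio (excluding the move-selection probabilities, returned
#' separately as `log_move_ratio`), and `log_jacobian` the log absolute
#' determinant of the deterministic transform.
#'
#' @inheritParams propose_parameter_move
#' @param kind one of `"split"`, `"merge"`, `"g-split"`, `"g-merge"`.
#' @param schedule a [move_schedule()]; the post-burn-in row supplies the
#'   move-selection probabilities of the ratio.
#' @return As [propose_parameter_move()], plus `log_move_ratio`.
#' @export
propose_split_merge <- function(params, kind = c("split", "merge", "g-split", "g-merge"),
                                priors, jumps = jump_sizes(), calib,
                                schedule = move_schedule()) {
  kind <- match.arg(kind)
  id <- match(kind, move_names())
  propose_impl(params, id, priors, jumps, calib, schedule["burnin", ])
}

#' Propose a birth or death move
#'
#' `birth` appends one emitter drawn from the prior (so the prior density
#' cancels in the acceptance ratio); `death` removes a uniformly chosen
#' emitter with the matching reverse density.
#'
#' @inheritParams propose_split_merge
#' @param kind `"birth"` or `"death"`.
#' @return As [propose_split_merge()].
#' @export
propose_birth_death <- function(params, kind = c("birth", "death"),
                                priors, calib, schedule = move_schedule()) {
  kind <- match.arg(kind)
  id <- match(kind, move_names())
  propose_impl(params, id, priors, jump_sizes(), calib, schedule["burnin", ])
}

default_row <- function() move_schedule()["burnin", ]

#' Metropolis-Hastings-Green acceptance
#'
#' Accepts the proposal with probability
#' `min(1, exp(llr + lpr + lqr + lj))`; a total of `-Inf` always rejects and
#' a `NaN` total is a hard error (it signals a model bug, not an unlucky
#' proposal).
#'
#' @param state,proposal current and proposed [frame_params()].
#' @param log_lik_ratio,log_prior_ratio,log_q_ratio,log_jacobian the log
#'   ratios of the acceptance probability.
#' @return A list with `state` (the new state) and `accepted`.
#' @export
accept_move <- function(state, proposal, log_lik_ratio, log_prior_ratio,
                        log_q_ratio = 0, log_jacobian = 0) {
  total <- log_lik_ratio + log_prior_ratio + log_q_ratio + log_jacobian
  if (is.nan(total)) stop("NaN acceptance ratio (model bug)")
  accepted <- if (total >= 0) TRUE else log(stats::runif(1)) < total
  list(state = if (accepted) proposal else state, accepted = accepted)
}
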