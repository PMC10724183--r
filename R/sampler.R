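#' Run the reversible-jump sampler on one frame
#'
#' Samples from the joint posterior of the emitter count and parameters
#' given a photon-count frame, using the nine-move RJMCMC kernel: random-walk
#' parameter moves (single emitter, overlap group, background) and
#' trans-dimensional moves (split/merge, prior-based g-split/g-merge,
#' birth/death), accepted by the Metropolis-Hastings-Green rule. The first
#' `n_burn` iterations use the burn-in move schedule (more model-space
#' mixing), the remainder the post-burn-in schedule.
#'
#' The chain starts from a background-only state (`k = 0`, background drawn
#' from its prior) unless `init` is given: model-space moves then build the
#' model up, so every accepted emitter is supported by the data. Starting
#' from a prior draw with several emitters can strand the chain in an
#' overfitted local mode whose escape (a coordinated merge-and-background
#' move) the move set does not provide; see the methods vignette.
#'
#' @param frame an [smlm_frame()] (or an integer matrix).
#' @param calib a [psf_calibration()].
#' @param priors a [prior_set()].
#' @param schedule a [move_schedule()].
#' @param jumps a [jump_sizes()].
#' @param n_iter total RJMCMC iterations.
#' @param n_burn burn-in iterations (must be < `n_iter`).
#' @param seed integer seed; every chain is bit-reproducible given the seed.
#' @param init optional initial [frame_params()].
#' @return An object of class `smlm_chain`: per-iteration records `k`,
#'   `move`, `accepted`, `phase` (`"burnin"`/`"post"`), `log_posterior`, `b`
#'   and the emitter matrix `theta` (columns `x1, y1, z1, I1, x2, ...`,
#'   `NA`-padded beyond the current `k`), plus the run metadata.
#' @export
run_rjmcmc <- function(frame, calib, priors, schedule = move_schedule(),
                       jumps = jump_sizes(), n_iter = 30000, n_burn = 10000,
                       seed = NULL, init = NULL) {
  if (is.matrix(frame)) frame <- smlm_frame(frame)
  stopifnot(inherits(frame, "smlm_frame"), n_iter > 0, n_burn >= 0, n_burn < n_iter)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- sample_prior(priors, 0)
  res <- cpp_run_chain(frame$planes, calib_vec(calib), prior_vec(priors),
                       unclass(schedule), jumps_vec(jumps),
                       as.integer(n_iter), as.integer(n_burn),
                       FALSE, as_state(init))
  new_chain(res, frame, calib, priors, schedule, jumps, seed,
            budget = c(n_iter = n_iter, n_burn = n_burn), kind = "rjmcmc")
}

#' Run the fixed-dimension MCMC conditioned on a model
#'
#' Samples `P(theta | k, D)` with the emitter count held fixed, using only
#' parameter-space moves (the `mcmc` row of the schedule). Conditioning on the
#' MAP model avoids mixing parameter samples across models of different
#' dimension.
#'
#' @inheritParams run_rjmcmc
#' @param k_fixed the conditioned emitter count.
#' @param init initial [frame_params()] with `k == k_fixed`.
#' @param n_iter MCMC iterations.
#' @return An `smlm_chain` (phase `"mcmc"` throughout, constant `k`).
#' @export
run_mcmc <- function(frame, calib, priors, k_fixed, init,
                     schedule = move_schedule(), jumps = jump_sizes(),
                     n_iter = 5000, seed = NULL) {
  if (is.matrix(frame)) frame <- smlm_frame(frame)
  stopifnot(inherits(init, "frame_params"))
  if (init$k != k_fixed) stop("init has k = ", init$k, ", expected ", k_fixed)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_chain(frame$planes, calib_vec(calib), prior_vec(priors),
                       unclass(schedule), jumps_vec(jumps),
                       as.integer(n_iter), 0L, TRUE, as_state(init))
  new_chain(res, frame, calib, priors, schedule, jumps, seed,
            budget = c(n_iter = n_iter, n_burn = 0), kind = "mcmc")
}

new_chain <- function(res, frame, calib, priors, schedule, jumps, seed,
                      budget, kind) {
  kmax <- priors$k_range[2]
  theta <- res$theta
  if (kmax > 0)
    colnames(theta) <- paste0(rep(c("x", "y", "z", "I"), kmax),
                              rep(seq_len(kmax), each = 4))
  phase <- c("burnin", "post", "mcmc")[res$phase + 1]
  structure(list(
    k = res$k, move = move_names()[res$move],
    accepted = as.logical(res$accepted), phase = phase,
    log_posterior = res$log_posterior, b = res$b, theta = theta,
    final_state = state_to_params(res$final_state),
    kind = kind, seed = seed, budget = budget,
    schedule = schedule, jumps = jumps, calib = calib, priors = priors,
    roi_shape = frame$roi_shape
  ), class = "smlm_chain")
}

#' @export
print.smlm_chain <- function(x, ...) {
  n <- length(x$k)
  cat(sprintf("smlm_chain (%s): %d iterations, seed %s\n", x$kind, n,
              if (is.null(x$seed)) "<none>" else x$seed))
  post <- x$phase != "burnin"
  tab <- table(factor(x$k[post]))
  cat("  post-burn-in k distribution:\n")
  print(round(tab / sum(tab), 3))
  cat(sprintf("  overall acceptance rate %.2f\n", mean(x$accepted)))
  invisible(x)
}

#' Flatten a chain to a data frame
#'
#' One row per iteration with the scalar records; emitter parameters stay in
#' the `theta` matrix columns.
#'
#' @param x an `smlm_chain`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.smlm_chain <- function(x, ...) {
  data.frame(iteration = seq_along(x$k), phase = x$phase, move = x$move,
             accepted = x$accepted, k = x$k, b = x$b,
             log_posterior = x$log_posterior, x$theta)
}

#' Per-move acceptance rates of a chain
#'
#' @param chain an `smlm_chain`.
#' @param phase optionally restrict to `"burnin"`, `"post"` or `"mcmc"`.
#' @return A named numeric vector of acceptance rates by move type.
#' @export
acceptance_rates <- function(chain, phase = NULL) {
  keep <- if (is.null(phase)) rep(TRUE, length(chain$move)) else chain$phase == phase
  tapply(chain$accepted[keep], chain$move[keep], mean)
}

#' Pooled MCMC position/intensity samples of a chain
#'
#' Stacks the per-emitter samples (one row per emitter per iteration) of the
#' selected phase; emitters are exchangeable, so samples are treated as a
#' point cloud.
#'
#' @param chain an `smlm_chain`.
#' @param phase which phase to pool (default: everything but burn-in).
#' @return A matrix with columns `x`, `y`, `z`, `I`.
#' @export
chain_samples <- function(chain, phase = c("post", "mcmc")) {
  keep <- chain$phase %in% phase
  th <- chain$theta[keep, , drop = FALSE]
  kmax <- ncol(th) / 4
  out <- do.call(rbind, lapply(seq_len(kmax), function(j) {
    m <- th[, (4 * j - 3):(4 * j), drop = FALSE]
    m[!is.na(m[, 1]), , drop = FALSE]
  }))
  colnames(out) <- c("x", "y", "z", "I")
  out
}
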