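#' Fit the multi-emitter model to one frame
#'
#' The package's main fitting routine. An RJMCMC run samples the joint
#' posterior of the emitter count and parameters; the maximum a posteriori
#' (MAP) count is selected from the post-burn-in samples; and a second,
#' fixed-dimension MCMC run conditions the parameter posterior on that model,
#' started from the best-scoring visited state of that dimension. The MCMC
#' samples are what the histogram reconstructions and localization tables
#' use.
#'
#' @param frame an [smlm_frame()] or integer photon-count matrix.
#' @param calib a [psf_calibration()].
#' @param priors a [prior_set()]; defaults to uniform priors with the P0
#'   intensity preset.
#' @param schedule a [move_schedule()].
#' @param jumps a [jump_sizes()].
#' @param n_rjmcmc,n_burn,n_mcmc iteration budget of the two runs.
#' @param n_chains number of independent RJMCMC chains whose post-burn-in
#'   samples are pooled for model selection. Trans-dimensional chains can
#'   take long excursions into locally self-consistent over-fitted models
#'   (see the methods vignette); independent restarts rarely take the same
#'   excursion at the same time, so pooling makes the MAP model robust at a
#'   fixed total budget.
#' @param seed integer seed controlling the whole fit.
#' @param keep_chains keep the full RJMCMC chains on the returned object.
#'   Each 30k-iteration chain holds a few MB of samples, so batch runs over
#'   many frames ([run_experiment()]) drop them and keep only the pooled
#'   model histogram and the conditioned MCMC chain.
#' @return An object of class `emitter_fit` with elements `map_k`, `rjmcmc`
#'   and `mcmc` (the two `smlm_chain`s), `estimate` (posterior-mean
#'   [frame_params()] under the MAP model, emitters ordered by x), and the
#'   inputs. Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `logLik`, `simulate`, `plot`.
#' @examples
#' calib <- astigmatic_calibration()
#' truth <- frame_params(x = 10.3, y = 9.8, z = 0, I = 2000, b = 20)
#' fr <- simulate_frame(truth, calib, roi = 20, seed = 7)
#' fit <- fit_emitters(fr, calib, n_rjmcmc = 3000, n_burn = 1000,
#'                     n_mcmc = 1000, seed = 7)
#' fit$map_k
#' coef(fit)
#' @export
fit_emitters <- function(frame, calib, priors = NULL,
                         schedule = move_schedule(), jumps = jump_sizes(),
                         n_rjmcmc = 30000, n_burn = 10000, n_mcmc = 5000,
                         n_chains = 4, seed = NULL, keep_chains = TRUE) {
  if (is.matrix(frame)) frame <- smlm_frame(frame)
  if (is.null(priors))
    priors <- prior_set(calib, frame$roi_shape, intensity_prior_preset("P0"))
  if (!is.null(seed)) set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(i)
    run_rjmcmc(frame, calib, priors, schedule, jumps,
               n_iter = n_rjmcmc, n_burn = n_burn))
  # A chain can spend its whole run in a locally self-consistent overfitted
  # model it cannot leave (see the methods vignette). Such chains never visit
  # the dominant mode, which shows as a clearly lower best log-posterior;
  # only chains within `lp_window` of the best chain vote on the model.
  lp_window <- 10
  best_lps <- vapply(chains, function(ch)
    max(ch$log_posterior[ch$phase != "burnin"]), numeric(1))
  use <- best_lps >= max(best_lps) - lp_window
  k_pool <- unlist(lapply(chains[use], function(ch)
    inroi_counts(ch)[ch$phase != "burnin"]))
  k_hat <- map_model(k_pool)
  # Condition the MCMC run on the last state of the selected dimension: a
  # posterior-distributed draw, so when the posterior is multimodal the
  # conditioned chain starts in each mode with its posterior weight.
  init <- NULL
  for (ch in chains[use]) {
    st <- tryCatch(last_state(ch, k_hat), error = function(e) NULL)
    if (!is.null(st)) { init <- st; break }
  }
  if (is.null(init)) {
    for (ch in chains) {
      st <- tryCatch(last_state(ch, k_hat), error = function(e) NULL)
      if (!is.null(st)) { init <- st; break }
    }
  }
  if (is.null(init)) stop("no chain visited an in-ROI count of ", k_hat)
  mc <- run_mcmc(frame, calib, priors, k_fixed = k_hat, init = init,
                 schedule = schedule, jumps = jumps, n_iter = n_mcmc)
  est <- posterior_mean_params(mc, k_hat)
  k_table <- table(factor(k_pool, levels = 0:priors$k_range[2]))
  rj_samples <- do.call(rbind, lapply(chains[use], rj_model_samples,
                                      k_hat = k_hat, thin = 10))
  structure(list(map_k = k_hat, rj_samples = rj_samples,
                 rjmcmc = if (keep_chains) chains[[1]] else NULL,
                 rjmcmc_chains = if (keep_chains) chains else NULL,
                 k_posterior = k_table / sum(k_table),
                 chain_best_lp = best_lps, chains_used = use,
                 mcmc = mc, estimate = est,
                 frame = frame, calib = calib, priors = priors,
                 schedule = schedule, jumps = jumps, seed = seed),
            class = "emitter_fit")
}

# thinned in-ROI emitter samples of the post-burn-in iterations whose
# in-ROI count equals the selected model. Unlike the basin-frozen
# conditioned MCMC run, the trans-dimensional chain crosses between
# degenerate modes, so these samples carry the posterior's mode weights;
# the separability analyses count modes on them.
rj_model_samples <- function(chain, k_hat, thin = 10) {
  cnt <- inroi_counts(chain)
  idx <- which(cnt == k_hat & chain$phase != "burnin")
  if (length(idx) == 0) return(NULL)
  idx <- idx[seq(1, length(idx), by = thin)]
  th <- chain$theta[idx, , drop = FALSE]
  roi <- chain$roi_shape
  kmax <- ncol(th) / 4
  out <- do.call(rbind, lapply(seq_len(kmax), function(j) {
    m <- th[, (4 * j - 3):(4 * j), drop = FALSE]
    keep <- !is.na(m[, 1]) & m[, 1] >= 0 & m[, 1] < roi[1] &
            m[, 2] >= 0 & m[, 2] < roi[2]
    m[keep, , drop = FALSE]
  }))
  colnames(out) <- c("x", "y", "z", "I")
  out
}

# last post-burn-in state whose in-ROI emitter count is k_hat; emitters
# outside the ROI are dropped so the conditioned run has exactly k_hat
last_state <- function(chain, k_hat) {
  cnt <- inroi_counts(chain)
  idx <- which(cnt == k_hat & chain$phase != "burnin")
  if (length(idx) == 0) idx <- which(cnt == k_hat)
  if (length(idx) == 0) stop("chain never visited an in-ROI count of ", k_hat)
  it <- idx[length(idx)]
  out <- params_at(chain, it, within_roi = TRUE)
  attr(out, "log_posterior") <- chain$log_posterior[it]
  out
}

# highest-log-posterior visited state whose in-ROI emitter count is k_hat
# (post-burn-in preferred); emitters outside the ROI are dropped so the
# conditioned run has exactly k_hat emitters
best_state <- function(chain, k_hat) {
  cnt <- inroi_counts(chain)
  idx <- which(cnt == k_hat & chain$phase != "burnin")
  if (length(idx) == 0) idx <- which(cnt == k_hat)
  if (length(idx) == 0) stop("chain never visited an in-ROI count of ", k_hat)
  it <- idx[which.max(chain$log_posterior[idx])]
  out <- params_at(chain, it, within_roi = TRUE)
  attr(out, "log_posterior") <- chain$log_posterior[it]
  out
}

params_at <- function(chain, it, within_roi = FALSE) {
  k <- chain$k[it]
  if (k == 0) return(frame_params(b = chain$b[it]))
  th <- chain$theta[it, , drop = TRUE]
  j <- seq_len(k)
  x <- th[4 * j - 3]; y <- th[4 * j - 2]; z <- th[4 * j - 1]; I <- th[4 * j]
  if (within_roi) {
    roi <- chain$roi_shape
    keep <- x >= 0 & x < roi[1] & y >= 0 & y < roi[2]
    x <- x[keep]; y <- y[keep]; z <- z[keep]; I <- I[keep]
  }
  frame_params(x, y, z, I, b = chain$b[it])
}

# posterior means under the fixed-k chain; emitter identity is only
# meaningful within the fixed-dimension run (no label switching across moves
# of a well-separated mode, but see the vignette for the multimodal caveat)
posterior_mean_params <- function(chain, k) {
  b <- mean(chain$b)
  if (k == 0) return(frame_params(b = b))
  th <- chain$theta[, seq_len(4 * k), drop = FALSE]
  m <- colMeans(th)
  j <- seq_len(k)
  ord <- order(m[4 * j - 3])
  frame_params(m[4 * j - 3][ord], m[4 * j - 2][ord], m[4 * j - 1][ord],
               m[4 * j][ord], b = b)
}

#' @export
print.emitter_fit <- function(x, ...) {
  cat("emitter_fit: MAP model k =", x$map_k, "\n")
  print(x$estimate)
  invisible(x)
}

#' @export
summary.emitter_fit <- function(object, ...) {
  s <- chain_samples(object$mcmc, "mcmc")
  psd <- if (nrow(s) > 0) apply(s, 2, stats::sd) else NULL
  out <- list(map_k = object$map_k, k_posterior = object$k_posterior,
              estimate = object$estimate, posterior_sd = psd,
              acceptance = acceptance_rates(object$mcmc),
              chi_square = chi_square_test(object$frame,
                                           predict(object),
                                           n_param = 4 * object$map_k + 1))
  class(out) <- "summary.emitter_fit"
  out
}

#' @export
print.summary.emitter_fit <- function(x, ...) {
  cat("MAP emitter count:", x$map_k, "\n")
  cat("posterior over k:\n"); print(round(x$k_posterior, 3))
  cat("posterior-mean estimate:\n"); print(x$estimate)
  if (!is.null(x$posterior_sd)) {
    cat("pooled posterior sd (x, y px; z um; I photons):\n")
    print(round(x$posterior_sd, 4))
  }
  cat(sprintf("chi-square %.1f vs threshold %.1f (dof %d): %s\n",
              x$chi_square$statistic, x$chi_square$threshold, x$chi_square$dof,
              if (x$chi_square$representative) "representative" else "not representative"))
  invisible(x)
}

#' @export
coef.emitter_fit <- function(object, ...) {
  e <- object$estimate
  if (e$k == 0) return(c(b = e$b))
  m <- cbind(x = e$x, y = e$y, z = e$z, I = e$I)
  rownames(m) <- paste0("emitter", seq_len(e$k))
  attr(m, "background") <- e$b
  m
}

#' Expected counts under the fitted parameters
#' @param object an `emitter_fit`.
#' @param params optionally a different [frame_params()] to evaluate.
#' @param ... unused.
#' @return List of per-plane expected-count matrices.
#' @export
predict.emitter_fit <- function(object, params = object$estimate, ...) {
  expected_counts(params, object$calib, object$frame$roi_shape)
}

#' Pearson residuals of the fitted frame
#' @param object an `emitter_fit`.
#' @param ... unused.
#' @return List of per-plane `(D - mu)/sqrt(mu)` matrices.
#' @export
residuals.emitter_fit <- function(object, ...) {
  mu <- predict(object)
  mapply(function(D, m) (D - m) / sqrt(m), object$frame$planes, mu,
         SIMPLIFY = FALSE)
}

#' @export
logLik.emitter_fit <- function(object, ...) {
  ll <- log_likelihood(object$frame, predict(object))
  attr(ll, "df") <- 4 * object$map_k + 1
  class(ll) <- "logLik"
  ll
}

#' Simulate frames from the fitted parameters
#' @param object an `emitter_fit`.
#' @param nsim number of frames.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of [smlm_frame()]s.
#' @export
simulate.emitter_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_frame(object$estimate, object$calib, object$frame$roi_shape,
                   seed = if (is.null(seed)) NULL else seed + i - 1))
}

#' Plot the posterior reconstruction of a fit
#' @param x an `emitter_fit`.
#' @param plane `"xy"` or `"xz"`.
#' @param ... passed to [plot.smlm_histogram()].
#' @export
plot.emitter_fit <- function(x, plane = "xy", ...) {
  plot(reconstruct(x$mcmc, plane = plane), ...)
}
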