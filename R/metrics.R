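#' Autocorrelation of a chain series
#'
#' Normalised autocorrelation at lags `0..max_lag`. Lag 0 is 1 by
#' construction. A constant series has no defined autocorrelation; it is
#' flagged with `NA` values and a `constant` attribute rather than an error,
#' since model chains legitimately go constant (e.g. `k` after convergence).
#'
#' @param series numeric vector (e.g. a chain's `k` or a parameter column).
#' @param max_lag largest lag, < `length(series)`.
#' @return Numeric vector of length `max_lag + 1`, names `lag0..lagL`.
#' @export
autocorrelation <- function(series, max_lag = 100) {
  n <- length(series)
  if (max_lag >= n) stop("series must be longer than max_lag")
  m <- mean(series)
  c0 <- sum((series - m)^2) / n
  lags <- 0:max_lag
  if (c0 == 0) {
    out <- rep(NA_real_, max_lag + 1)
    names(out) <- paste0("lag", lags)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- vapply(lags, function(l) {
    sum((series[1:(n - l)] - m) * (series[(1 + l):n] - m)) / n / c0
  }, numeric(1))
  names(out) <- paste0("lag", lags)
  out
}

# d sigma / d z of the width model at depth z
dwidth_dz <- function(s0, g, d, A, z) {
  u <- (z - g) / d
  R <- 1 + u^2 + A * u^3
  s0 * (2 * u + 3 * A * u^2) / (2 * d * sqrt(R))
}

# per-axis integrated fractions and their derivatives wrt position and width
axis_terms <- function(pos, sigma, n) {
  e <- (0:n - pos) / sigma
  cdf <- stats::pnorm(e)
  pdf <- stats::dnorm(e)
  list(F = diff(cdf),
       dpos = -(pdf[-1] - pdf[-(n + 1)]) / sigma,
       dsig = -((e * pdf)[-1] - (e * pdf)[-(n + 1)]) / sigma)
}

#' Cramer-Rao lower bound for the Poisson image model
#'
#' Fisher information \eqn{I_{ab} = \sum_i (\partial\mu_i/\partial\theta_a)
#' (\partial\mu_i/\partial\theta_b) / \mu_i} with analytic derivatives of the
#' pixel-integrated Gaussian (the same model the likelihood uses), summed
#' over planes. The bound is the square root of the diagonal of its inverse.
#'
#' @param params a [frame_params()].
#' @param calib a [psf_calibration()].
#' @param roi ROI size.
#' @return A list with `crlb` (named vector: `x1, y1, z1, I1, ..., b`; x/y in
#'   pixels, z in micrometres, I and b in photons), `fisher` (the information
#'   matrix) and `gradients`.
#' @export
crlb <- function(params, calib, roi) {
  roi <- as.integer(rep(roi, length.out = 2))
  nx <- roi[1]; ny <- roi[2]
  k <- params$k
  npar <- 4 * k + 1
  nplanes <- length(calib$plane_offsets)
  mu <- expected_counts(params, calib, roi)
  G <- vector("list", nplanes)
  for (p in seq_len(nplanes)) {
    pf <- calib$plane_fractions[p]
    grads <- matrix(0, nx * ny, npar)
    for (j in seq_len(k)) {
      zz <- params$z[j] - calib$plane_offsets[p]
      sx <- width_at_depth(c(calib$s0_x, calib$gamma_x, calib$d_x, calib$A_x), zz)
      sy <- width_at_depth(c(calib$s0_y, calib$gamma_y, calib$d_y, calib$A_y), zz)
      ax <- axis_terms(params$x[j], sx, nx)
      ay <- axis_terms(params$y[j], sy, ny)
      dsx <- dwidth_dz(calib$s0_x, calib$gamma_x, calib$d_x, calib$A_x, zz)
      dsy <- dwidth_dz(calib$s0_y, calib$gamma_y, calib$d_y, calib$A_y, zz)
      I <- params$I[j]
      grads[, 4 * j - 3] <- pf * I * as.vector(outer(ax$dpos, ay$F))
      grads[, 4 * j - 2] <- pf * I * as.vector(outer(ax$F, ay$dpos))
      grads[, 4 * j - 1] <- pf * I * as.vector(outer(ax$dsig * dsx, ay$F) +
                                               outer(ax$F, ay$dsig * dsy))
      grads[, 4 * j]     <- pf * as.vector(outer(ax$F, ay$F))
    }
    grads[, npar] <- pf
    G[[p]] <- grads
  }
  fisher <- matrix(0, npar, npar)
  for (p in seq_len(nplanes)) {
    w <- 1 / as.vector(mu[[p]])
    fisher <- fisher + crossprod(G[[p]] * sqrt(w))
  }
  nm <- c(if (k > 0) paste0(rep(c("x", "y", "z", "I"), k), rep(seq_len(k), each = 4)),
          "b")
  dimnames(fisher) <- list(nm, nm)
  inv <- tryCatch(solve(fisher), error = function(e)
    stop("singular Fisher information matrix"))
  bound <- sqrt(diag(inv))
  names(bound) <- nm
  list(crlb = bound, fisher = fisher, gradients = G)
}

#' Precision report: posterior spread vs truth vs CRLB
#'
#' For a set of single-emitter fits with known truths, summarises per
#' intensity bin the posterior standard deviation, the RMSE of the posterior
#' mean against the truth, and the CRLB evaluated at the truth. Bins where
#' the posterior spread exceeds the bound by more than `flag_factor` are
#' flagged.
#'
#' @param fits list of [fit_emitters()] results (MAP k = 1 expected).
#' @param truths list of true [frame_params()], aligned with `fits`.
#' @param calib a [psf_calibration()].
#' @param n_bins number of intensity bins.
#' @param flag_factor flag threshold on posterior sd / CRLB.
#' @param pixel_size_nm pixel size used for nm-scale reporting columns.
#' @return A data frame of class `precision_report` with one row per
#'   intensity bin and parameter.
#' @export
precision_report <- function(fits, truths, calib, n_bins = 3, flag_factor = 1.5,
                             pixel_size_nm = 100) {
  if (length(fits) == 0) stop("no chains supplied")
  stopifnot(length(fits) == length(truths))
  per <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; tr <- truths[[i]]
    if (f$map_k != 1 || tr$k != 1) return(NULL)
    s <- chain_samples(f$mcmc, "mcmc")
    bd <- crlb(tr, calib, f$frame$roi_shape)$crlb
    data.frame(I_true = tr$I,
               param = c("x", "y", "z", "I"),
               post_sd = apply(s, 2, stats::sd),
               err = c(mean(s[, "x"]) - tr$x, mean(s[, "y"]) - tr$y,
                       mean(s[, "z"]) - tr$z, mean(s[, "I"]) - tr$I),
               crlb = bd[c("x1", "y1", "z1", "I1")])
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no single-emitter fits to report on")
  brk <- stats::quantile(per$I_true, probs = seq(0, 1, length.out = n_bins + 1))
  brk[1] <- brk[1] - 1e-9
  per$bin <- cut(per$I_true, breaks = unique(brk), include.lowest = TRUE)
  agg <- do.call(rbind, lapply(split(per, list(per$bin, per$param), drop = TRUE),
    function(d) data.frame(
      bin = d$bin[1], param = d$param[1], n = nrow(d),
      mean_I = mean(d$I_true),
      post_sd = mean(d$post_sd),
      rmse = sqrt(mean(d$err^2)),
      crlb = mean(d$crlb))))
  agg$flagged <- agg$post_sd > flag_factor * agg$crlb
  agg$post_sd_nm <- ifelse(agg$param %in% c("x", "y"), agg$post_sd * pixel_size_nm,
                    ifelse(agg$param == "z", agg$post_sd * 1000, NA))
  rownames(agg) <- NULL
  class(agg) <- c("precision_report", "data.frame")
  agg
}
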