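test_that("autocorrelation has unit lag zero and known AR(1) decay", {
  set.seed(14)
  x <- rnorm(4000)
  ac <- autocorrelation(x, 20)
  expect_equal(unname(ac["lag0"]), 1)
  expect_true(all(abs(ac[-1]) < 2 / sqrt(4000) * 2.5))
  # AR(1) with coefficient rho decays as rho^lag
  rho <- 0.8
  y <- as.numeric(arima.sim(list(ar = rho), 20000))
  acy <- autocorrelation(y, 10)
  expect_equal(unname(acy[paste0("lag", 1:5)]), rho^(1:5), tolerance = 0.1)
  # constant series: flagged, not an error
  const <- autocorrelation(rep(3, 100), 5)
  expect_true(all(is.na(const)))
  expect_true(attr(const, "constant"))
  expect_error(autocorrelation(1:5, 10), "longer")
})

test_that("Fisher-information gradients match finite differences", {
  calib <- astigmatic_calibration()
  p <- frame_params(9.7, 10.4, 0.3, 1800, 15)
  cr <- crlb(p, calib, 20)
  grads <- cr$gradients[[1]]
  eps <- 1e-5
  mu_of <- function(par) as.vector(expected_counts(par, calib, 20)[[1]])
  bump <- function(field, delta) {
    q <- p; q[[field]] <- q[[field]] + delta; q
  }
  for (i in seq_along(c(x = 1, y = 2, z = 3, I = 4))) {
    field <- c("x", "y", "z", "I")[i]
    fd <- (mu_of(bump(field, eps)) - mu_of(bump(field, -eps))) / (2 * eps)
    expect_equal(grads[, i], fd, tolerance = 1e-6)
  }
  fd_b <- (mu_of(bump("b", eps)) - mu_of(bump("b", -eps))) / (2 * eps)
  expect_equal(grads[, 5], fd_b, tolerance = 1e-8)
})

test_that("the bound shrinks with photons and never improves by removing them", {
  calib <- astigmatic_calibration()
  lo <- crlb(frame_params(10, 10, 0, 1000, 20), calib, 20)$crlb
  hi <- crlb(frame_params(10, 10, 0, 2000, 20), calib, 20)$crlb
  expect_lt(hi["x1"], lo["x1"])
  expect_lt(hi["z1"], lo["z1"])
  ladder <- vapply(c(500, 1000, 2000, 4000), function(I)
    crlb(frame_params(10, 10, 0, I, 20), calib, 20)$crlb["x1"], numeric(1))
  expect_true(all(diff(ladder) < 0))
})

test_that("single-emitter posterior spread reaches the bound at high signal", {
  calib <- astigmatic_calibration()
  # wide flat intensity prior so the posterior is likelihood-dominated
  pri <- prior_set(calib, 20, intensity_prior(2000, 1000))
  truth <- frame_params(10.3, 9.8, 0, 2000, 20)
  fr <- simulate_frame(truth, calib, 20, seed = 7)
  fit <- fit_emitters(fr, calib, pri, n_mcmc = 8000, seed = 7)
  expect_equal(fit$map_k, 1)
  s <- chain_samples(fit$mcmc, "mcmc")
  bd <- crlb(truth, calib, 20)$crlb
  expect_equal(sd(s[, "x"]), unname(bd["x1"]), tolerance = 0.12)
  expect_equal(sd(s[, "y"]), unname(bd["y1"]), tolerance = 0.12)
  expect_equal(sd(s[, "z"]), unname(bd["z1"]), tolerance = 0.12)
  expect_gt(sd(s[, "x"]), 0.9 * bd["x1"]) # no super-efficiency
})

test_that("precision reports flag bias and validate their inputs", {
  calib <- astigmatic_calibration()
  pri <- prior_set(calib, 20, intensity_prior(2000, 1000))
  fits <- list(); truths <- list()
  for (i in 1:3) {
    truths[[i]] <- frame_params(9.5 + 0.3 * i, 10.2, 0, 2000, 20)
    fr <- simulate_frame(truths[[i]], calib, 20, seed = 30 + i)
    fits[[i]] <- fit_emitters(fr, calib, pri, n_rjmcmc = 8000, n_burn = 3000,
                              n_mcmc = 2000, seed = 40 + i)
  }
  rep <- precision_report(fits, truths, calib, n_bins = 1)
  expect_s3_class(rep, "data.frame")
  expect_true(all(c("post_sd", "rmse", "crlb", "flagged") %in% names(rep)))
  expect_true(all(rep$crlb > 0))
  # a deliberately biased truth: RMSE exceeds the posterior spread
  shifted <- truths
  shifted[[1]] <- frame_params(truths[[1]]$x + 1, truths[[1]]$y, 0, 2000, 20)
  rep2 <- precision_report(fits[1], shifted[1], calib, n_bins = 1)
  expect_true(all(rep2$rmse[rep2$param == "x"] >
                    rep2$post_sd[rep2$param == "x"]))
  expect_error(precision_report(list(), list(), calib), "no chains")
})
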