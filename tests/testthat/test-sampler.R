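test_that("chains are bit-reproducible under a fixed seed", {
  calib <- toy_calib()
  pri <- toy_priors()
  fr <- simulate_frame(frame_params(0.9, 1.2, 0.05, 30, 3), calib, 2, seed = 11)
  a <- run_rjmcmc(fr, calib, pri, jumps = toy_jumps(), n_iter = 2000,
                  n_burn = 500, seed = 21)
  b <- run_rjmcmc(fr, calib, pri, jumps = toy_jumps(), n_iter = 2000,
                  n_burn = 500, seed = 21)
  expect_identical(a$k, b$k)
  expect_identical(a$theta, b$theta)
  expect_identical(a$log_posterior, b$log_posterior)
})

test_that("the sampler matches a brute-force posterior oracle on an enumerable toy", {
  # 2x2-pixel frame, k in 0..3. The oracle estimates each model's marginal
  # likelihood by prior Monte Carlo integration (independent of the chain);
  # the chain's k-marginal must agree in total variation.
  calib <- toy_calib()
  pri <- toy_priors(k_max = 3)
  truth <- frame_params(0.9, 1.2, 0.05, 30, 3)
  fr <- simulate_frame(truth, calib, 2, seed = 11)
  D <- as.vector(fr$planes[[1]])
  lgD <- sum(lgamma(D + 1))
  set.seed(42)
  draw_contrib <- function(n) {
    x <- runif(n, 0, 2); y <- runif(n, 0, 2); z <- runif(n, -0.2, 0.2)
    I <- rintensity(n, pri$intensity)
    sz <- 0.8 * sqrt(1 + (z / 0.5)^2)
    fx1 <- pnorm((1 - x) / sz) - pnorm((0 - x) / sz)
    fx2 <- pnorm((2 - x) / sz) - pnorm((1 - x) / sz)
    fy1 <- pnorm((1 - y) / sz) - pnorm((0 - y) / sz)
    fy2 <- pnorm((2 - y) / sz) - pnorm((1 - y) / sz)
    cbind(I * fx1 * fy1, I * fx2 * fy1, I * fx1 * fy2, I * fx2 * fy2)
  }
  marg <- function(k, n = 1e6) {
    b <- runif(n, 1, 10)
    mu <- matrix(rep(b, 4), n, 4)
    if (k > 0) for (j in 1:k) mu <- mu + draw_contrib(n)
    mean(exp(D[1] * log(mu[, 1]) + D[2] * log(mu[, 2]) +
             D[3] * log(mu[, 3]) + D[4] * log(mu[, 4]) - rowSums(mu) - lgD))
  }
  L <- vapply(0:3, marg, numeric(1))
  oracle <- L / sum(L)
  ch <- run_rjmcmc(fr, calib, pri, jumps = toy_jumps(), n_iter = 1.5e5,
                   n_burn = 2e4, seed = 5)
  emp <- tabulate(ch$k[ch$phase != "burnin"] + 1, 4) /
    sum(ch$phase != "burnin")
  expect_lt(sum(abs(emp - oracle)) / 2, 0.05)
  # parameter marginal: x-posterior of the k = 1 model vs a grid oracle
  keep <- ch$phase != "burnin" & ch$k == 1
  xs <- ch$theta[keep, "x1"]
  gx <- seq(0.05, 1.95, by = 0.1)
  post_x <- vapply(gx, function(x0) {
    n <- 4e4
    y <- runif(n, 0, 2); z <- runif(n, -0.2, 0.2)
    I <- rintensity(n, pri$intensity); b <- runif(n, 1, 10)
    sz <- 0.8 * sqrt(1 + (z / 0.5)^2)
    fx1 <- pnorm((1 - x0) / sz) - pnorm((0 - x0) / sz)
    fx2 <- pnorm((2 - x0) / sz) - pnorm((1 - x0) / sz)
    fy1 <- pnorm((1 - y) / sz) - pnorm((0 - y) / sz)
    fy2 <- pnorm((2 - y) / sz) - pnorm((1 - y) / sz)
    mu <- cbind(I * fx1 * fy1 + b, I * fx2 * fy1 + b,
                I * fx1 * fy2 + b, I * fx2 * fy2 + b)
    mean(exp(D[1] * log(mu[, 1]) + D[2] * log(mu[, 2]) +
             D[3] * log(mu[, 3]) + D[4] * log(mu[, 4]) - rowSums(mu) - lgD))
  }, numeric(1))
  post_x <- post_x / sum(post_x)
  emp_x <- tabulate(findInterval(xs, seq(0, 2, by = 0.1),
                                 all.inside = TRUE), 20) / length(xs)
  expect_lt(sum(abs(emp_x - post_x)) / 2, 0.05)
})

test_that("a background-only frame selects the empty model", {
  calib <- toy_calib()
  pri <- toy_priors()
  fr <- simulate_frame(frame_params(b = 4), calib, 2, seed = 13)
  ch <- run_rjmcmc(fr, calib, pri, jumps = toy_jumps(), n_iter = 3e4,
                   n_burn = 5e3, seed = 31)
  expect_equal(map_model(ch), 0)
})

test_that("a bright single emitter is identified as one emitter", {
  calib <- astigmatic_calibration()
  pri <- astig_priors()
  for (s in 1:3) {
    truth <- frame_params(9.6 + 0.3 * s, 10.2, 0, 2000, 20)
    fr <- simulate_frame(truth, calib, 20, seed = 100 + s)
    fit <- fit_emitters(fr, calib, pri, n_rjmcmc = 10000, n_burn = 4000,
                        n_mcmc = 1000, seed = 200 + s)
    expect_equal(fit$map_k, 1)
    # posterior means recover the truth within a few posterior sds
    est <- fit$estimate
    expect_lt(abs(est$x - truth$x), 0.2)
    expect_lt(abs(est$y - truth$y), 0.2)
  }
})

test_that("the conditioned MCMC run keeps the model fixed", {
  calib <- astigmatic_calibration()
  pri <- astig_priors()
  fr <- simulate_frame(frame_params(10, 10, 0, 2000, 20), calib, 20, seed = 1)
  init <- frame_params(10.1, 9.9, 0.05, 1950, 21)
  ch <- run_mcmc(fr, calib, pri, k_fixed = 1, init = init, n_iter = 3000,
                 seed = 77)
  expect_true(all(ch$k == 1))
  expect_true(all(ch$move %in% c("single", "group", "background")))
  expect_error(run_mcmc(fr, calib, pri, k_fixed = 2, init = init), "expected")
})

test_that("with no emitters the background posterior matches the Poisson MLE", {
  calib <- toy_calib()
  pri <- toy_priors()
  fr <- simulate_frame(frame_params(b = 6), calib, 2, seed = 17)
  ch <- run_mcmc(fr, calib, pri, k_fixed = 0, init = frame_params(b = 5),
                 jumps = toy_jumps(), n_iter = 2e4, seed = 19)
  expect_equal(mean(ch$b[-(1:2000)]), mean(fr$planes[[1]]), tolerance = 0.1)
})
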