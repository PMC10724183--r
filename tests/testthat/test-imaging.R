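test_that("expected counts follow the linear Poisson image model", {
  calib <- astigmatic_calibration()
  # background-only frame: constant expectation
  mu0 <- expected_counts(frame_params(b = 20), calib, 20)
  expect_equal(unique(as.vector(mu0[[1]])), 20)
  # one centred in-focus emitter captures nearly all photons in the ROI
  p1 <- frame_params(10, 10, 0, 2000, 20)
  mu1 <- expected_counts(p1, calib, 20)
  expect_equal(sum(mu1[[1]] - 20), 2000, tolerance = 2) # out-of-ROI tail
  # two-emitter expectation is the emitter-wise sum (linearity)
  pa <- frame_params(8.8, 10, 0, 2000, 20)
  pb <- frame_params(11.2, 10, 0, 2000, 20)
  pab <- frame_params(c(8.8, 11.2), c(10, 10), c(0, 0), c(2000, 2000), 20)
  expect_equal(expected_counts(pab, calib, 20)[[1]],
               expected_counts(pa, calib, 20)[[1]] +
                 expected_counts(pb, calib, 20)[[1]] - 20,
               tolerance = 1e-12)
})

test_that("biplane splitting conserves total intensity and background", {
  calib <- biplane_calibration()
  p <- frame_params(c(14, 16), c(15, 15), c(0.1, -0.2), c(2000, 1500), 20)
  mu <- expected_counts(p, calib, 30)
  expect_length(mu, 2)
  # per-plane background is half of 20 photons/px; total signal over both
  # planes recovers the summed emitter intensities up to the out-of-ROI tail
  expect_equal(min(unlist(mu)), 10, tolerance = 0.2)
  signal <- sum(unlist(mu)) - 20 * 30 * 30 # total background over both planes
  expect_equal(signal, 3500, tolerance = 5)
})

test_that("log-likelihood equals the Poisson log pmf summed over pixels", {
  expect_equal(log_likelihood(matrix(0L), matrix(1)), -1)
  expect_equal(log_likelihood(matrix(1L), matrix(1)), -1)
  set.seed(3)
  D <- matrix(rpois(30, 5), 5, 6)
  mu <- matrix(runif(30, 2, 9), 5, 6)
  expect_equal(log_likelihood(D, mu), sum(dpois(D, mu, log = TRUE)),
               tolerance = 1e-10)
  # biplane frames multiply likelihoods across planes
  fr <- smlm_frame(list(D, D))
  expect_equal(log_likelihood(fr, list(mu, mu)),
               2 * sum(dpois(D, mu, log = TRUE)), tolerance = 1e-10)
  expect_error(log_likelihood(D, mu[1:4, ]), "mismatch")
})

test_that("constant-expectation likelihood is maximised at the sample mean", {
  set.seed(5)
  D <- matrix(rpois(100, 7), 10, 10)
  ll <- function(m) log_likelihood(D, matrix(m, 10, 10))
  m_hat <- mean(D)
  expect_gt(ll(m_hat), ll(m_hat * 1.05))
  expect_gt(ll(m_hat), ll(m_hat * 0.95))
})

test_that("ADU conversion applies the elementwise camera model", {
  raw <- matrix(c(100, 110, 95, 130), 2, 2)
  fr <- adu_to_photons(raw, gain = 2, offset = 100)
  expect_equal(as.vector(fr$planes[[1]]), c(0, 5, 0, 15)) # clipped at zero
  # identity on non-negative integers
  m <- matrix(0:8, 3, 3)
  expect_equal(adu_to_photons(m, gain = 1, offset = 0)$planes[[1]],
               matrix(as.integer(m), 3, 3))
  set.seed(8)
  r <- matrix(runif(25, 0, 500), 5, 5)
  fr2 <- adu_to_photons(r, gain = 1.7, offset = 30)
  expect_equal(as.vector(fr2$planes[[1]]),
               pmax(0, round((as.vector(r) - 30) / 1.7)))
  expect_error(adu_to_photons(raw, gain = 0), "gain")
})

test_that("frame containers validate their invariants", {
  expect_error(smlm_frame(matrix(-1L, 2, 2)), "non-negative")
  expect_error(smlm_frame(list(matrix(0L, 2, 2), matrix(0L, 3, 3))), "shape")
  expect_error(frame_params(1, 1, 0, -5, 1))
  p <- frame_params(c(1, 2), c(1, 2), c(0, 0), c(10, 20), 2)
  expect_equal(p$k, 2)
})
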