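test_that("MAP model selection is the post-burn-in mode with parsimony ties", {
  expect_equal(map_model(c(1L, 1L, 2L, 1L)), 1L)
  expect_equal(map_model(c(2L, 2L, 3L, 3L)), 2L) # tie toward smaller k
  expect_error(map_model(integer(0)), "samples")
})

test_that("model accuracy is the matching fraction", {
  expect_equal(model_accuracy(c(rep(2L, 98), 1L, 3L), 2), 0.98)
  expect_equal(model_accuracy(rep(1L, 5), 1), 1)
  expect_equal(model_accuracy(rep(3L, 5), 1), 0)
  expect_error(model_accuracy(integer(0), 1), "empty")
})

make_point_chain <- function(pts, roi = 20, z_range = c(-1.3, 1.3)) {
  # minimal smlm_chain carrying given (x, y, z) samples for one emitter
  n <- nrow(pts)
  theta <- cbind(x1 = pts[, 1], y1 = pts[, 2], z1 = pts[, 3], I1 = 2000)
  structure(list(
    k = rep(1L, n), move = rep("single", n), accepted = rep(TRUE, n),
    phase = rep("mcmc", n), log_posterior = numeric(n), b = rep(20, n),
    theta = theta, kind = "mcmc", seed = 1,
    budget = c(n_iter = n, n_burn = 0),
    priors = list(axial = z_range), roi_shape = c(roi, roi)
  ), class = "smlm_chain")
}

test_that("reconstruction geometry and mass conservation hold", {
  pts <- cbind(rep(10.21, 500), rep(9.44, 500), rep(0, 500))
  ch <- make_point_chain(pts)
  h <- reconstruct(ch, "xy", magnification = 2.5)
  expect_equal(dim(unclass(h)), c(50, 50)) # 20 px at 2.5 bins per pixel
  expect_equal(sum(h), 500)
  expect_equal(sum(h > 0), 1) # all samples in a single bin
  # pooled mass over several chains
  set.seed(2)
  chains <- lapply(1:3, function(i)
    make_point_chain(cbind(runif(200, 2, 18), runif(200, 2, 18), 0)))
  expect_equal(sum(reconstruct(chains, "xy")), 600)
  h3 <- reconstruct(chains, "xyz", magnification = 2, z_bins = 10)
  expect_equal(sum(h3), 600)
  expect_equal(dim(unclass(h3)), c(40, 40, 10))
})

blob_chain <- function(centers, n_per = 400, sd = 0.15, z = 0) {
  set.seed(99)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd),
          rnorm(n_per, z, 0.05))))
  make_point_chain(pts)
}

test_that("mode counting resolves blob layouts and ignores magnification", {
  one <- blob_chain(matrix(c(10, 10), 1))
  expect_equal(as.integer(count_modes(reconstruct(one, "xy"))), 1)
  two <- blob_chain(matrix(c(7, 10, 13, 10), 2, byrow = TRUE))
  expect_equal(as.integer(count_modes(reconstruct(two, "xy"))), 2)
  # four-blob layout mimicking the degenerate two-pair pattern
  four <- blob_chain(matrix(c(8.2, 10, 11.8, 10, 10, 8.2, 10, 11.8),
                            4, byrow = TRUE))
  expect_equal(as.integer(count_modes(reconstruct(four, "xy"))), 4)
  # same count at camera resolution and at 2.5x magnification
  expect_equal(as.integer(count_modes(reconstruct(two, "xy", magnification = 1))),
               as.integer(count_modes(reconstruct(two, "xy", magnification = 2.5))))
  # 3D counting separates laterally coincident blobs at different depths
  set.seed(98)
  deep <- rbind(
    cbind(rnorm(400, 10, 0.15), rnorm(400, 10, 0.15), rnorm(400, 0, 0.05)),
    cbind(rnorm(400, 10, 0.15), rnorm(400, 10, 0.15), rnorm(400, -0.9, 0.05)))
  ch3 <- make_point_chain(deep)
  expect_equal(as.integer(count_modes(reconstruct(ch3, "xy"))), 1)
  expect_equal(as.integer(count_modes(reconstruct(ch3, "xyz", z_bins = 20),
                                      min_separation = 3)), 2)
})

test_that("k-means clustering finds separated blobs and collapses tight clouds", {
  set.seed(12)
  blobs <- rbind(cbind(rnorm(500, 7, 0.2), rnorm(500, 10, 0.2)),
                 cbind(rnorm(500, 13, 0.2), rnorm(500, 10, 0.2)))
  colnames(blobs) <- c("x", "y")
  km <- cluster_modes(blobs, 2, seed = 3)
  expect_equal(unname(sort(km$centers[, "x"])), c(7, 13), tolerance = 0.05)
  expect_equal(km$center_separation, 6, tolerance = 0.05)
  # a single tight cloud: the two requested centres nearly coincide
  cloud <- cbind(x = rnorm(800, 10, 0.25), y = rnorm(800, 10, 0.25))
  km2 <- cluster_modes(cloud, 2, seed = 3)
  expect_lt(km2$center_separation, 0.8)
  expect_error(cluster_modes(cloud[c(1, 1), ], 3, seed = 1), "distinct")
  # deterministic under a fixed seed
  expect_identical(cluster_modes(blobs, 2, seed = 3)$centers, km$centers)
})

test_that("chi-square representativeness follows the Pearson statistic", {
  mu <- matrix(10, 10, 10)
  D <- matrix(10L, 10, 10)
  r <- chi_square_test(D, mu, n_param = 5)
  expect_equal(r$statistic, 0)
  expect_equal(r$dof, 95)
  expect_true(r$representative)
  expect_equal(r$threshold, qchisq(0.95, 95))
  # at the true expectation the statistic concentrates near its dof
  set.seed(21)
  stats <- replicate(200, {
    d <- matrix(rpois(400, 50), 20, 20)
    chi_square_test(d, matrix(50, 20, 20))$statistic
  })
  expect_equal(mean(stats), 400, tolerance = 0.03)
})

test_that("mode confusion is symmetric, half for identical modes, zero when distinct", {
  calib <- astigmatic_calibration()
  a <- frame_params(c(9, 11), c(10, 10), c(0, 0), c(2000, 2000), 20)
  expect_equal(mode_error_probability(a, a, calib, 20, n_sim = 2000, seed = 1),
               0.5, tolerance = 0.05)
  b <- frame_params(c(4, 16), c(4, 4), c(0, 0), c(2000, 2000), 20)
  expect_lt(mode_error_probability(a, b, calib, 20, n_sim = 500, seed = 1), 0.001)
  c1 <- frame_params(c(9, 11), c(10, 10), c(0.1, 0), c(1900, 2100), 20)
  p_ab <- mode_error_probability(a, c1, calib, 20, n_sim = 4000, seed = 2)
  p_ba <- mode_error_probability(c1, a, calib, 20, n_sim = 4000, seed = 3)
  expect_equal(p_ab, p_ba, tolerance = 0.1)
})

test_that("the KL-matched alternate mode is perpendicular and below focus", {
  calib <- astigmatic_calibration()
  tp <- two_emitter_truth(0.75)
  alt <- find_alternate_mode(tp, calib, 20)
  # perpendicular: the true pair separates along x, the ghost along y
  expect_equal(diff(alt$params$x), 0, tolerance = 1e-6)
  expect_gt(abs(diff(alt$params$y)), 0.3)
  # below the focal plane, and nearly indistinguishable in expectation
  expect_lt(alt$z_um, -0.1)
  expect_lt(alt$kl, 0.1)
})
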