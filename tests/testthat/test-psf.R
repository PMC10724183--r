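test_that("width model hits its closed-form anchor points", {
  # at the focal offset the width is s0; one depth-of-focus away it is s0*sqrt(2)
  expect_equal(width_at_depth(c(1.2, 2, 3, 0), 2), 1.2)
  expect_equal(width_at_depth(c(1.2, 2, 3, 0), 5), 1.2 * sqrt(2))
  # direct scalar evaluation of the biplane calibration at z = 0
  u <- (0 - (-0.464)) / 0.834
  expect_equal(width_at_depth(biplane_calibration(), 0, axis = "x"),
               1.70 * sqrt(1 + u^2))
  # vectorised
  z <- c(-1, 0, 1)
  expect_equal(width_at_depth(c(1, 0, 0.5, 0), z), sqrt(1 + (z / 0.5)^2))
})

test_that("invalid radicands are a domain error, not a number", {
  # strong negative cubic coefficient drives the radicand negative
  expect_error(width_at_depth(c(1, 0, 0.3, -2), 1), "radicand")
})

test_that("with no cubic term the width grows monotonically away from focus", {
  z <- seq(-1.3, 1.3, by = 0.05)
  w <- width_at_depth(c(1.2, 0.3, 0.8, 0), z)
  expect_true(all(diff(w[z < 0.3]) < 0))
  expect_true(all(diff(w[z > 0.3]) > 0))
})

test_that("pixel fractions integrate the Gaussian exactly over pixels", {
  calib <- toy_calib()
  # emitter on the shared corner of four pixels with isotropic width:
  # the four adjacent pixels carry equal mass
  f <- pixel_fractions(1, 1, 0, calib, 2)[[1]]
  expect_equal(f[1, 1], f[2, 2])
  expect_equal(f[1, 2], f[2, 1])
  expect_equal(f[1, 1], f[1, 2])
  # normalization over a grid extending far beyond the emitter
  big <- psf_calibration(1.2, 0, 1, 0, z_range = c(-1, 1), plane_offsets = 0)
  tot <- sum(pixel_fractions(20, 20, 0.5, big, 40)[[1]])
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("pixel fractions match 2D numerical quadrature", {
  skip_if_not_installed("pracma")
  calib <- astigmatic_calibration()
  set.seed(7)
  for (r in 1:4) {
    x <- runif(1, 3, 5); y <- runif(1, 3, 5); z <- runif(1, -1, 1)
    f <- pixel_fractions(x, y, z, calib, 8)[[1]]
    sx <- width_at_depth(calib, z, "x")
    sy <- width_at_depth(calib, z, "y")
    dens <- function(u, v)
      exp(-((u - x)^2 / (2 * sx^2) + (v - y)^2 / (2 * sy^2))) / (2 * pi * sx * sy)
    for (px in list(c(3, 3), c(4, 3), c(5, 4))) {
      q <- pracma::integral2(dens, px[1], px[1] + 1, px[2], px[2] + 1,
                             reltol = 1e-10)$Q
      expect_equal(f[px[1] + 1, px[2] + 1], q, tolerance = 1e-8)
    }
  }
})

test_that("biplane fractions split photons by the plane fractions", {
  calib <- biplane_calibration()
  f <- pixel_fractions(15, 15, 0.2, calib, 30)
  expect_length(f, 2)
  expect_equal(sum(f[[1]]) + sum(f[[2]]), 1, tolerance = 1e-4)
  # even split
  expect_equal(sum(f[[1]]), sum(f[[2]]), tolerance = 1e-4)
})

test_that("z-scan shows the astigmatic elongation axis flipping across focus", {
  calib <- astigmatic_calibration()
  zs <- render_zscan(calib, c(-1.2, 0, 1.2), 21)
  expect_length(zs, 3)
  spread <- function(m) {
    w <- m / sum(m)
    i <- row(m) - 11; j <- col(m) - 11
    c(x = sum(w * i^2), y = sum(w * j^2))
  }
  s_lo <- spread(zs[[1]][[1]])
  s_hi <- spread(zs[[3]][[1]])
  # below focus x-elongated, above focus y-elongated (gamma_x = +2 um)
  expect_gt(s_lo["x"], s_lo["y"])
  expect_lt(s_hi["x"], s_hi["y"])
  # mirrored depths are x/y transposes of each other (gamma_y = -gamma_x, A = 0)
  expect_equal(zs[[1]][[1]], t(zs[[3]][[1]]), tolerance = 1e-12)
})

test_that("calibration constructor validates its invariants", {
  expect_error(psf_calibration(-1, 0, 1, 0), "s0_x")
  expect_error(psf_calibration(1, 0, 1, 0, z_range = c(1, -1)))
  expect_error(psf_calibration(1, 0, 1, 0, modality = "biplane",
                               plane_offsets = 0), "length 2")
  expect_error(psf_calibration(1, 0, 1, 0, modality = "biplane",
                               plane_offsets = c(0.15, -0.15),
                               plane_fractions = c(0.7, 0.6)), "sum to 1")
  # axial unit conversion: px declares 100 nm units
  cal <- psf_calibration(1.2, 2, 3, 0, axial_unit = "px")
  expect_equal(cal$gamma_x, 0.2)
  expect_equal(cal$d_x, 0.3)
})
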