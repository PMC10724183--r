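test_that("the default move schedules are exact probability vectors", {
  sch <- move_schedule()
  expect_equal(rowSums(sch), c(burnin = 1, post = 1, mcmc = 1))
  expect_true(all(sch["mcmc", 4:9] == 0))
  expect_error(move_schedule(mcmc = c(0.3, 0.3, 0.2, 0.2, 0, 0, 0, 0, 0)),
               "model-space")
  expect_error(move_schedule(burnin = rep(0.1, 9)), "sum to 1")
})

test_that("random-walk proposals have the configured step scales", {
  pri <- astig_priors()
  calib <- astigmatic_calibration()
  jm <- jump_sizes()
  state <- frame_params(c(9, 11), c(10, 10), c(0, 0), c(2000, 2000), 20)
  set.seed(4)
  n <- 4000
  dx <- dz <- dI <- db <- numeric(n)
  for (r in seq_len(n)) {
    p <- propose_parameter_move(state, "single", jm, pri, calib)$params
    j <- which(p$x != state$x)[1]
    dx[r] <- p$x[j] - state$x[j]
    dz[r] <- p$z[j] - state$z[j]
    dI[r] <- p$I[j] - state$I[j]
    db[r] <- propose_parameter_move(state, "background", jm, pri, calib)$params$b - 20
  }
  expect_equal(sd(dx), jm$sigma_x, tolerance = 0.05)
  expect_equal(sd(dz), jm$sigma_z, tolerance = 0.05)
  expect_equal(sd(dI), jm$sigma_I, tolerance = 0.05)
  expect_equal(sd(db), jm$sigma_b, tolerance = 0.05)
})

test_that("background and group moves touch only what they should", {
  pri <- astig_priors()
  calib <- astigmatic_calibration()
  state <- frame_params(c(9, 11), c(10, 10), c(0, 0), c(2000, 2000), 20)
  set.seed(5)
  pb <- propose_parameter_move(state, "background", jump_sizes(), pri, calib)
  expect_identical(pb$params$x, state$x)
  expect_identical(pb$params$I, state$I)
  expect_false(pb$params$b == state$b)
  # group move translates the overlapping pair rigidly
  pg <- propose_parameter_move(state, "group", jump_sizes(), pri, calib)
  shift <- pg$params$x - state$x
  expect_equal(shift[1], shift[2], tolerance = 1e-12)
  expect_identical(pg$params$I, state$I)
  # no emitters: auto-rejected no-op
  p0 <- propose_parameter_move(frame_params(b = 5), "single", jump_sizes(),
                               pri, calib)
  expect_false(p0$valid)
})

test_that("split conserves intensity and centroid; merge is its exact inverse", {
  pri <- astig_priors()
  calib <- astigmatic_calibration()
  state <- frame_params(10.3, 9.7, 0.2, 2000, 20)
  set.seed(6)
  for (r in 1:20) {
    sp <- propose_split_merge(state, "split", pri, jump_sizes(), calib)
    if (!sp$valid) next
    p <- sp$params
    expect_equal(p$k, 2)
    expect_equal(sum(p$I), 2000, tolerance = 1e-10)
    f <- p$I / sum(p$I)
    expect_equal(sum(f * p$x), 10.3, tolerance = 1e-10)
    expect_equal(sum(f * p$y), 9.7, tolerance = 1e-10)
    expect_equal(sum(f * p$z), 0.2, tolerance = 1e-10)
    expect_equal(sp$log_jacobian, log(2000), tolerance = 1e-12)
    # merging the pair recovers the original state exactly
    mg <- propose_split_merge(p, "merge", pri, jump_sizes(), calib)
    expect_equal(mg$params$x, state$x, tolerance = 1e-10)
    expect_equal(mg$params$y, state$y, tolerance = 1e-10)
    expect_equal(mg$params$z, state$z, tolerance = 1e-10)
    expect_equal(mg$params$I, state$I, tolerance = 1e-10)
    expect_equal(mg$log_jacobian, -log(2000), tolerance = 1e-12)
    # and the proposal-density ratios cancel on the round trip
    expect_equal(sp$log_q_ratio + mg$log_q_ratio, 0, tolerance = 1e-10)
  }
})

test_that("birth and death respect the prior support and preconditions", {
  pri <- astig_priors()
  calib <- astigmatic_calibration()
  set.seed(7)
  b <- propose_birth_death(frame_params(b = 10), "birth", pri, calib)
  expect_equal(b$params$k, 1)
  expect_true(is.finite(log_prior(b$params, pri)))
  d <- propose_birth_death(b$params, "death", pri, calib)
  expect_equal(d$params$k, 0)
  expect_equal(d$params$b, b$params$b)
  expect_false(propose_birth_death(frame_params(b = 10), "death", pri, calib)$valid)
  full <- sample_prior(pri, 6)
  expect_false(propose_birth_death(full, "birth", pri, calib)$valid)
})

test_that("acceptance follows the Metropolis-Hastings-Green rule", {
  s <- frame_params(b = 5); p <- frame_params(b = 6)
  # total log ratio zero: always accept
  for (r in 1:10) expect_true(accept_move(s, p, 0, 0)$accepted)
  # impossible proposals never accepted
  for (r in 1:10) expect_false(accept_move(s, p, -Inf, 0)$accepted)
  expect_error(accept_move(s, p, NaN, 0), "NaN")
  # empirical acceptance frequency equals exp(total) at a fixed ratio
  set.seed(8)
  r <- -1.2
  acc <- mean(replicate(20000, accept_move(s, p, r, 0)$accepted))
  expect_equal(acc, exp(r), tolerance = 4 * sqrt(exp(r) / 20000) / exp(r))
})
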