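test_that("the observation matrix has the documented structure", {
  m3 <- build_kalman_model(sensor_array(c(0.015, 0.025, 0.035)))
  expect_identical(m3$F, diag(3))
  expect_identical(m3$B, diag(3))
  expect_equal(m3$H[1, ], c(-1, 1, 0))
  expect_equal(m3$H[2, ], c(0, -1, 1))
  # constraint row for pair (1,2): +D2 in column 1, -D1 in column 2
  expect_equal(m3$H[3, ], c(0.025, -0.015, 0))
  expect_equal(m3$H[4, ], c(0, 0.035, -0.025))
  m2 <- build_kalman_model(sensor_array(c(0.015, 0.025)),
                           constraint_pairs = NULL)
  expect_equal(m2$H, matrix(c(-1, 1), 1))
  expect_error(build_kalman_model(sensor_array(c(0.015, 0.025, 0.035)),
                                  list(c(1, 2), c(1, 2))), "duplicate")
})

test_that("prediction adds the control input and inflates the covariance", {
  s <- kalman_state(c(3e-4, 5e-4), diag(1e-12, 2))
  p <- kalman_predict(s, c(-1e-5, -1.67e-5), c(1e-13, 1e-13))
  expect_equal(p$T, c(2.9e-4, 4.833e-4), tolerance = 1e-9)
  expect_equal(diag(p$P), rep(1.1e-12, 2))
  # repeated prediction without update grows P linearly
  for (k in 1:5) p <- kalman_predict(p, c(0, 0), c(1e-13, 1e-13))
  expect_equal(diag(p$P), rep(1.6e-12, 2))
  expect_error(kalman_predict(s, c(0, 0), c(0, 1e-13)), "positive")
})

test_that("a single update equals batch generalized-least-squares fusion", {
  set.seed(41)
  arr <- sensor_array(c(0.015, 0.025, 0.035))
  model <- build_kalman_model(arr)
  for (rep in 1:5) {
    T0 <- c(3, 5, 7) * 1e-4 + rnorm(3, 0, 1e-5)
    A <- matrix(rnorm(9, 0, 1e-6), 3)
    P0 <- A %*% t(A) + diag(1e-11, 3)
    z <- c(2e-4 + rnorm(1, 0, 1e-5), 2e-4 + rnorm(1, 0, 1e-5), 0, 0)
    R <- c(1e-11, 1e-11, 1e-13, 1e-13)
    post <- kalman_update(kalman_state(T0, P0), model, z, R)
    oracle <- gls_fuse(T0, P0, model$H, z, R)
    expect_equal(post$T, oracle$T, tolerance = 1e-9)
    expect_equal(post$P, oracle$P, tolerance = 1e-9)
  }
})

test_that("uninformative and exact observations behave as limits", {
  model <- build_kalman_model(sensor_array(c(0.015, 0.025)),
                              constraint_pairs = NULL)
  s <- kalman_state(c(3e-4, 5e-4), diag(1e-12, 2))
  post <- kalman_update(s, model, 2.5e-4, 1e2)
  expect_equal(post$T, s$T, tolerance = 1e-12)
  expect_equal(post$P, s$P, tolerance = 1e-13)
  # noiseless z = H T_true with tiny R pulls the observed combination exact
  T_true <- c(3e-4, 6e-4)
  post2 <- kalman_update(kalman_state(c(2e-4, 9e-4), diag(1e-8, 2)), model,
                         drop(model$H %*% T_true), 1e-22)
  expect_equal(drop(model$H %*% post2$T), drop(model$H %*% T_true),
               tolerance = 1e-9)
})

test_that("posterior variances never exceed their priors", {
  set.seed(42)
  arr <- sensor_array(c(0.015, 0.025, 0.035, 0.045))
  model <- build_kalman_model(arr)
  s <- kalman_state((arr$positions / 50), diag(1e-11, 4))
  for (k in 1:50) {
    s <- kalman_predict(s, rnorm(4, 0, 1e-6), rep(1e-13, 4))
    prior_diag <- diag(s$P)
    z <- c(rnorm(3, 2e-4, 1e-5), 0, 0, 0)
    s <- kalman_update(s, model, z, c(rep(1e-11, 3), rep(1e-12, 3)))
    expect_true(all(diag(s$P) <= prior_diag + 1e-15))
    expect_true(all(eigen(s$P, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
  }
})

test_that("with constraints off and huge R the filter dead-reckons", {
  model <- build_kalman_model(sensor_array(c(0.015, 0.025)),
                              constraint_pairs = NULL)
  s <- kalman_state(c(3e-4, 5e-4), diag(1e-12, 2))
  T_expect <- s$T
  set.seed(43)
  for (k in 1:10) {
    u <- rnorm(2, 0, 1e-6)
    T_expect <- T_expect + u
    s <- kalman_predict(s, u, rep(1e-13, 2))
    s <- kalman_update(s, model, 2e-4, 1e6)
  }
  expect_equal(s$T, T_expect, tolerance = 1e-12)
})

test_that("weighted least squares speed matches the normal-equation oracle", {
  arr <- sensor_array(c(0.015, 0.025, 0.035))
  s <- kalman_state(c(3e-4, 5e-4, 7e-4), diag(1e-12, 3))
  expect_equal(speed_from_arrivals(arr, s)$speed, 50, tolerance = 1e-9)
  set.seed(44)
  arr4 <- sensor_array(c(0.015, 0.025, 0.035, 0.045))
  for (rep in 1:5) {
    T <- arr4$positions / 60 + rnorm(4, 0, 2e-5)
    w <- runif(4, 0.1, 10)
    est <- speed_from_arrivals(arr4, kalman_state(T, diag(1 / w)))
    expect_equal(est$speed, wls_slope(T, arr4$positions, w),
                 tolerance = 1e-9)
  }
  # one weight to (near) zero: slope collapses to the remaining two sensors
  T <- c(3e-4, 5e-4, 8e-4)
  est <- speed_from_arrivals(arr, kalman_state(T, diag(3)),
                             weights = c(1, 1, 1e-12))
  expect_equal(est$speed, 0.01 / 2e-4, tolerance = 1e-6)
  expect_error(speed_from_arrivals(arr, kalman_state(rep(1e-4, 3), diag(3))),
               "spread")
})

test_that("speed is invariant to a joint scaling of positions and arrivals", {
  set.seed(45)
  pos <- c(0.015, 0.025, 0.035)
  T <- pos / 55 + rnorm(3, 0, 1e-5)
  w <- runif(3, 0.5, 2)
  base <- speed_from_arrivals(sensor_array(pos), kalman_state(T, diag(1 / w)))
  for (k in c(0.5, 2, 10)) {
    scaled <- speed_from_arrivals(sensor_array(k * pos),
                                  kalman_state(k * T, diag(1 / w)))
    expect_equal(scaled$speed, base$speed, tolerance = 1e-9)
  }
})

test_that("the traditional estimator recovers constructed speeds", {
  arr2 <- sensor_array(c(0.015, 0.025))
  rec <- noiseless_tap(speed = 50, positions = arr2$positions)
  xc <- xcorr_only_speed(rec, arr2)
  expect_equal(xc$speed, 50, tolerance = 0.5)
  expect_false(xc$invalid)
  arr3 <- sensor_array(c(0.015, 0.025, 0.035))
  rec3 <- noiseless_tap(speed = 50, positions = arr3$positions)
  expect_equal(xcorr_only_speed(rec3, arr3)$speed, 50, tolerance = 0.5)
  # identical channels: the true zero delay lies outside the physical
  # search range, so the peak pins to the boundary and is flagged
  same <- rec
  same$samples[, 2] <- same$samples[, 1]
  expect_true(estimate_travel_time(same, 1, 2, arr2)$boundary)
})

test_that("noiseless filtering recovers a constant speed within 1%", {
  prof <- make_gait_profile("constant", peak_speed = 50)
  arr <- sensor_array(c(0.015, 0.025, 0.035))
  set.seed(46)
  st <- simulate_stride(prof, arr, tap_waveform_params(), noise_spec(Inf),
                        stride_duration = 0.3)
  res <- run_filter(st, arr, shared_vm())
  expect_true(all(abs(res$speeds$speed_kalman - 50) < 0.5))
  expect_true(all(abs(res$speeds$speed_xcorr - 50) < 0.5))
  # posterior variance stays bounded along the pass
  vlast <- vapply(res$states, function(s) max(diag(s$P)), 0)
  expect_lt(max(vlast[-1]), 10 * stats::median(vlast[-1]) + 1e-15)
})
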