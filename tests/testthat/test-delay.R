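test_that("normalized cross-correlation matches the naive per-lag formula", {
  set.seed(21)
  template <- rnorm(64)
  search <- rnorm(96)
  expect_equal(normalized_xcorr(template, search),
               naive_ncc(template, search), tolerance = 1e-12)
})

test_that("self- and anti-correlation identities hold", {
  set.seed(22)
  x <- rnorm(50)
  r <- normalized_xcorr(x, c(x, rnorm(20)))
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_equal(normalized_xcorr(x, -x)[1], -1, tolerance = 1e-12)
  expect_true(all(r >= -1 & r <= 1))
  expect_error(normalized_xcorr(rep(1, 10), rnorm(20)), "zero-variance")
})

test_that("cosine interpolation is exact on sampled pure cosines", {
  expect_equal(cosine_subsample(0.6, 0.9, 0.6), 0)
  w <- 0.8
  expect_equal(cosine_subsample(cos(w * (-1 - 0.3)), cos(w * (0 - 0.3)),
                                cos(w * (1 - 0.3))), 0.3, tolerance = 1e-9)
  expect_equal(cosine_subsample(cos(w * (-1 + 0.49)), cos(w * 0.49),
                                cos(w * (1 + 0.49))), -0.49, tolerance = 1e-9)
  # sweep of offsets and frequencies
  for (w in c(0.3, 1.0, 2.0)) {
    for (d in c(-0.45, -0.2, 0.1, 0.37)) {
      expect_equal(cosine_subsample(cos(w * (-1 - d)), cos(w * -d),
                                    cos(w * (1 - d))), d, tolerance = 1e-9)
    }
  }
  expect_error(cosine_subsample(1, 1, 1), class = "degenerate_fit")
})

test_that("noiseless travel time is recovered to sub-sample precision", {
  arr <- sensor_array(c(0.015, 0.025))
  rec <- noiseless_tap(speed = 50, positions = arr$positions)
  m <- estimate_travel_time(rec, 1, 2, arr)
  expect_lt(abs(m$shift - 2e-4), 2e-6)
  expect_gt(m$r, 0.999)
  expect_false(m$boundary)
  # non-integer sample delay too: 48 m/s -> 10.42 samples
  rec2 <- noiseless_tap(speed = 48, positions = arr$positions)
  m2 <- estimate_travel_time(rec2, 1, 2, arr)
  expect_lt(abs(m2$shift - 0.01 / 48), 2e-6)
  expect_error(estimate_travel_time(rec, 2, 2, arr), "distinct")
  expect_error(estimate_travel_time(rec, 2, 1, arr), "proximal")
})

test_that("pairwise travel times are additive on noiseless input", {
  arr <- sensor_array(c(0.015, 0.025, 0.035))
  rec <- noiseless_tap(speed = 43, positions = arr$positions)
  t12 <- estimate_travel_time(rec, 1, 2, arr)$shift
  t23 <- estimate_travel_time(rec, 2, 3, arr)$shift
  t13 <- estimate_travel_time(rec, 1, 3, arr)$shift
  expect_lt(abs(t12 + t23 - t13), 2 * 2e-6)
})

test_that("arrival change between identical taps is zero with r = 1", {
  rec <- noiseless_tap()
  m <- estimate_arrival_delta(rec, rec, 1)
  expect_equal(m$shift, 0)
  expect_equal(m$r, 1, tolerance = 1e-12)
})

test_that("a speed change shifts the arrival by the predicted amount", {
  pos <- c(0.015, 0.025)
  prev <- noiseless_tap(speed = 50, positions = pos)
  curr <- noiseless_tap(speed = 52, positions = pos)
  expected <- 0.025 / 52 - 0.025 / 50            # -19.23 us
  m <- estimate_arrival_delta(prev, curr, 2, prev_arrival = 0.025 / 50)
  expect_lt(abs(m$shift - expected), 2e-6)
  # approximate antisymmetry: swapping the taps negates the shift
  mr <- estimate_arrival_delta(curr, prev, 2, prev_arrival = 0.025 / 52)
  expect_lt(abs(mr$shift + m$shift), 2 * 2e-6)
})

test_that("travel-time estimates are unbiased under moderate noise", {
  arr <- sensor_array(c(0.015, 0.025))
  set.seed(23)
  n <- 300
  shifts <- vapply(seq_len(n), function(k) {
    rec <- synthesize_tap(50, arr, tap_waveform_params(), noise_spec(4))
    # operating configuration: template centred on the arrival estimate
    estimate_travel_time(rec, 1, 2, arr, template_anchor = 3e-4)$shift
  }, 0)
  se <- stats::sd(shifts) / sqrt(n)
  expect_lt(abs(mean(shifts) - 2e-4), 3 * se)
})

test_that("tap-to-tap windows correlate more strongly than inter-sensor ones", {
  set.seed(24)
  delta <- run_calibration(2, reps = 250, style = "delta")
  set.seed(24)
  tau <- run_calibration(2, reps = 250, style = "tau")
  expect_gte(delta$mean_r, tau$mean_r)
})

test_that("measurements export to a tidy data frame", {
  arr <- sensor_array(c(0.015, 0.025))
  rec <- noiseless_tap(speed = 50, positions = arr$positions)
  df <- delay_measurements_df(list(estimate_travel_time(rec, 1, 2, arr),
                                   estimate_arrival_delta(rec, rec, 1)),
                              tap_index = 1L)
  expect_identical(names(df), c("tap_index", "kind", "i", "j", "shift_s",
                                "r", "boundary_flag"))
  expect_identical(df$kind, c("travel-time", "arrival-change"))
})
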