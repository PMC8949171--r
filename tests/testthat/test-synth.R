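test_that("impulse response starts at zero and peaks at the set amplitude", {
  h <- second_order_impulse(tap_waveform_params(), 50000, 3e-3)
  expect_identical(h[1], 0)
  # the sampled grid straddles the true peak; evaluate on a fine grid
  hf <- second_order_impulse(tap_waveform_params(), 5e6, 3e-3)
  expect_equal(max(abs(hf)), 20, tolerance = 1e-6)
})

test_that("analytic impulse peak time matches a brute-force grid search", {
  for (zeta in c(0.3, 0.5, 0.7)) {
    tp_analytic <- tensiometry:::.sdof_peak_time(2 * pi * 1600, zeta)
    tp_grid <- brute_force_peak_time(1600, zeta)
    expect_lt(abs(tp_analytic - tp_grid), 2e-6)
  }
})

test_that("overdamped parameters are rejected", {
  expect_error(tap_waveform_params(damping_ratio = 1), "underdamped")
  expect_error(tap_waveform_params(damping_ratio = 1.2), "underdamped")
})

test_that("band-limited noise has the exact requested SD, zero mean", {
  expect_identical(band_limited_noise(100, 0), numeric(100))
  set.seed(1)
  x <- band_limited_noise(50000, 5)
  expect_equal(stats::sd(x), 5, tolerance = 1e-9)
  expect_lt(abs(mean(x)), 3 * 5 / sqrt(50000))
})

test_that("noise power outside the pass band is at least 20 dB down", {
  set.seed(2)
  x <- band_limited_noise(2e5, 1, band = c(100, 5000), sample_rate = 50000)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 50000), plot = FALSE,
                          spans = 51)
  inband <- mean(sp$spec[sp$freq > 300 & sp$freq < 4000])
  outband <- mean(sp$spec[sp$freq > 8000])
  expect_gt(10 * log10(inband / outband), 20)
})

test_that("noise band outside (0, Nyquist) is rejected", {
  expect_error(band_limited_noise(100, 1, band = c(100, 30000),
                                  sample_rate = 50000), "Nyquist")
})

test_that("synthesized taps carry exact analytic arrival times", {
  rec <- noiseless_tap(speed = 50, positions = c(0.015, 0.025))
  expect_equal(rec$truth$arrivals, c(3e-4, 5e-4))
  # integer-sample delay: distal channel is an exact shifted copy
  lag <- 10                                    # 0.2 ms at 50 kHz
  n <- nrow(rec$samples)
  expect_equal(rec$samples[(lag + 1):n, 2], rec$samples[1:(n - lag), 1],
               tolerance = 1e-12)
})

test_that("arrivals beyond the record raise a window error", {
  expect_error(noiseless_tap(speed = 5, positions = c(0.015, 0.045)),
               "exceeds the")
})

test_that("constructed inter-channel delay is recovered by the estimator", {
  rec <- noiseless_tap(speed = 50, positions = c(0.015, 0.025))
  m <- estimate_travel_time(rec, 1, 2, sensor_array(c(0.015, 0.025)))
  expect_lt(abs(m$shift - 2e-4), 2e-6)
})

test_that("gait profiles are deterministic with the documented shapes", {
  pc <- make_gait_profile("constant", peak_speed = 50)
  f <- seq(0, 0.99, by = 0.01)
  expect_true(all(pc$speed(f) == 50))
  pw <- make_gait_profile("walking")
  expect_equal(max(pw$speed(f)), 55, tolerance = 1e-6)
  expect_equal(f[which.max(pw$speed(f))], 0.48)
  expect_gt(min(pw$envelope(f)), 0.099)
  pw2 <- make_gait_profile("walking")
  expect_identical(pw$speed(f), pw2$speed(f))
  expect_error(make_gait_profile("hopping"))
})

test_that("position perturbation preserves ordering and has the right SD", {
  arr <- sensor_array(c(0.015, 0.025, 0.035))
  expect_identical(perturb_positions(arr, 0), arr)
  set.seed(3)
  draws <- replicate(4000, perturb_positions(arr, 5e-4)$positions - arr$positions)
  expect_lt(abs(stats::sd(draws) - 5e-4) / 5e-4, 0.05)
  set.seed(4)
  for (k in 1:100) {
    p <- perturb_positions(arr, 3e-3)$positions   # large SD forces redraws
    expect_true(all(diff(p) > 0))
  }
})

test_that("stride simulation matches the tapping schedule and draws", {
  prof <- make_gait_profile("constant", peak_speed = 50)
  arr <- sensor_array(c(0.015, 0.025))
  set.seed(5)
  st <- simulate_stride(prof, arr, tap_waveform_params(), noise_spec(Inf))
  expect_length(st$taps, 110)                    # round(1.1 s x 100 Hz)
  # zero parameter SDs + no noise: all taps identical
  set.seed(6)
  st0 <- simulate_stride(prof, arr,
                         tap_waveform_params(frequency_sd = 0, damping_sd = 0),
                         noise_spec(Inf), stride_duration = 0.05)
  for (k in 2:length(st0$taps)) {
    expect_identical(st0$taps[[k]]$samples, st0$taps[[1]]$samples)
  }
  # per-tap natural frequencies follow the stated between-tap distribution
  set.seed(7)
  st3 <- simulate_stride(prof, arr, tap_waveform_params(), noise_spec(Inf),
                         stride_duration = 3.3)
  fns <- vapply(st3$taps, function(tp) tp$truth$waveform$natural_frequency, 0)
  expect_equal(stats::sd(fns), 100, tolerance = 0.15)
  expect_equal(mean(fns), 1600, tolerance = 0.01)
})

test_that("simulation is bit-identical under a fixed seed", {
  prof <- make_gait_profile("walking")
  arr <- sensor_array(c(0.015, 0.025))
  set.seed(11)
  a <- simulate_stride(prof, arr, tap_waveform_params(), noise_spec(4),
                       stride_duration = 0.05)
  set.seed(11)
  b <- simulate_stride(prof, arr, tap_waveform_params(), noise_spec(4),
                       stride_duration = 0.05)
  expect_identical(lapply(a$taps, `[[`, "samples"),
                   lapply(b$taps, `[[`, "samples"))
})

test_that("noise realizations on distinct channels are independent", {
  set.seed(12)
  n <- 20000
  a <- band_limited_noise(n, 1)
  b <- band_limited_noise(n, 1)
  expect_lt(abs(stats::cor(a, b)), 0.05)
})
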