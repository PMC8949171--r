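# Independent oracles and shared fixtures for the test suite.

# naive per-lag Pearson correlation, the reference for the fast kernel
naive_ncc <- function(template, search) {
  m <- length(template)
  n_lag <- length(search) - m + 1
  vapply(seq_len(n_lag), function(k) {
    w <- search[k:(k + m - 1)]
    sum((template - mean(template)) * (w - mean(w))) /
      (sqrt(sum((template - mean(template))^2)) *
         sqrt(sum((w - mean(w))^2)))
  }, 0)
}

# brute-force peak time of the underdamped impulse response on a 1 us grid
brute_force_peak_time <- function(natural_frequency, damping_ratio,
                                  grid = 1e-6, horizon = 3e-3) {
  wn <- 2 * pi * natural_frequency
  wd <- wn * sqrt(1 - damping_ratio^2)
  t <- seq(grid, horizon, by = grid)
  h <- exp(-damping_ratio * wn * t) * sin(wd * t)
  t[which.max(abs(h))]
}

# batch generalized-least-squares fusion of a Gaussian prior with linear
# observations, by explicit normal equations (information form)
gls_fuse <- function(T_prior, P_prior, H, z, R) {
  Pinv <- solve(P_prior)
  Rinv <- diag(1 / R, length(R))
  P_post <- solve(Pinv + t(H) %*% Rinv %*% H)
  T_post <- P_post %*% (Pinv %*% T_prior + t(H) %*% Rinv %*% z)
  list(T = as.numeric(T_post), P = P_post)
}

# weighted least-squares slope by explicit normal equations
wls_slope <- function(x, y, w) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  b[2]
}

# a noiseless tap at a known speed for delay/speed tests
noiseless_tap <- function(speed = 50, positions = c(0.015, 0.025),
                          duration = 6e-3) {
  synthesize_tap(speed, sensor_array(positions),
                 tap_waveform_params(frequency_sd = 0, damping_sd = 0),
                 noise_spec(Inf), duration = duration)
}

# shared desk-scale variance model, calibrated once per test run
shared_vm <- local({
  vm <- NULL
  function() {
    if (is.null(vm)) {
      set.seed(4242)
      vm <<- default_variance_model(reps = 150)
    }
    vm
  }
})
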