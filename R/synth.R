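# Simulator for tensiometer recordings: each tap excites an underdamped
# second-order impulse response that propagates at the prescribed wave speed
# and is sensed, with band-limited Gaussian noise, by each accelerometer.

# cache Butterworth designs per (low, high, fs); filter design is ~ms-scale
# and would otherwise dominate tight simulation loops
.butter_cache <- new.env(parent = emptyenv())

.butter_coefs <- function(band, sample_rate) {
  key <- paste(band[1], band[2], sample_rate, sep = "|")
  cf <- .butter_cache[[key]]
  if (is.null(cf)) {
    nyq <- sample_rate / 2
    if (band[2] >= nyq) {
      stop(sprintf("noise band [%g, %g] Hz must lie below Nyquist (%g Hz)",
                   band[1], band[2], nyq), call. = FALSE)
    }
    bf <- signal::butter(4, band / nyq, type = "pass")
    cf <- list(b = as.numeric(bf$b), a = as.numeric(bf$a))
    .butter_cache[[key]] <- cf
  }
  cf
}

# peak time of e^(-zeta*wn*t) * sin(wd*t): first zero of the derivative
.sdof_peak_time <- function(wn, zeta) {
  wd <- wn * sqrt(1 - zeta^2)
  atan2(wd, zeta * wn) / wd
}

# gain making the peak absolute value equal `amplitude`
.sdof_gain <- function(wn, zeta, amplitude) {
  wd <- wn * sqrt(1 - zeta^2)
  tp <- .sdof_peak_time(wn, zeta)
  amplitude / (exp(-zeta * wn * tp) * sin(wd * tp))
}

#' Underdamped second-order impulse response
#'
#' Evaluates `h(t) = A exp(-zeta*wn*t) sin(wd*t)` with
#' `wd = wn*sqrt(1 - zeta^2)` on a uniform grid, with the gain `A` chosen so
#' the peak absolute value equals `params$amplitude`. `h(0) = 0`.
#'
#' @param params A [tap_waveform_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param duration Record duration, seconds (default 3 ms, several decay
#'   constants of the nominal response).
#' @return Numeric waveform of `round(duration * sample_rate)` samples, m/s^2.
#' @export
#' @examples
#' h <- second_order_impulse(tap_waveform_params(), 50000, 3e-3)
#' max(abs(h))   # 20 m/s^2 by construction
second_order_impulse <- function(params, sample_rate = 50000, duration = 3e-3) {
  stopifnot(inherits(params, "tap_waveform_params"), sample_rate > 0,
            duration > 0)
  wn <- 2 * pi * params$natural_frequency
  zeta <- params$damping_ratio
  n <- round(duration * sample_rate)
  t <- seq(0, by = 1 / sample_rate, length.out = n)
  .sdof_impulse_kernel(t, wn, zeta, .sdof_gain(wn, zeta, params$amplitude))
}

#' Band-limited Gaussian noise
#'
#' Zero-mean Gaussian white noise band-pass filtered with a 4th-order
#' Butterworth filter applied forward-backward (zero phase), then rescaled so
#' the empirical SD exactly equals `sd`.
#'
#' @param n_samples Number of samples.
#' @param sd Target standard deviation, m/s^2 (`0` yields silence).
#' @param band Pass band, Hz (low, high); must lie inside (0, Nyquist).
#' @param sample_rate Sampling rate, Hz.
#' @return Numeric waveform of length `n_samples`.
#' @export
band_limited_noise <- function(n_samples, sd, band = c(100, 5000),
                               sample_rate = 50000) {
  stopifnot(n_samples > 0, sd >= 0)
  if (sd == 0) return(numeric(n_samples))
  cf <- .butter_coefs(band, sample_rate)
  x <- .filtfilt_kernel(cf$b, cf$a, stats::rnorm(n_samples))
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

#' Simulated recording of a single tap
#'
#' Simulates one tap propagating at wave speed `speed` across the array:
#' channel `i` carries the impulse response delayed by `positions[i] / speed`
#' (realized analytically, so sub-sample delays are exact) plus independent
#' band-limited noise of SD `noise_ref_amplitude / snr`. All channels share
#' one waveform realization per tap (one physical wave).
#'
#' @param speed True shear-wave speed, m/s (> 0).
#' @param array A [sensor_array()].
#' @param params A [tap_waveform_params()] (its `amplitude` may already carry
#'   a gait envelope).
#' @param noise A [noise_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param duration Record length per tap, seconds (default 6 ms).
#' @param pre_roll Pre-trigger margin before the tap onset, seconds (default
#'   1 ms). Continuous acquisitions always carry pre-tap context; the margin
#'   lets arrival-change searches reach negative lags for early arrivals.
#' @param noise_ref_amplitude Reference amplitude defining the SNR, m/s^2;
#'   defaults to `params$amplitude`, so in gait simulations the noise floor
#'   tracks the tap's local signal amplitude and the per-tap SNR equals the
#'   prescribed level throughout the stride.
#' @return A `tap_recording`: list with `samples` (matrix, one column per
#'   channel), `sample_rate`, `tap_onset` (sample index of the excitation),
#'   and a `truth` block (`speed`, `arrivals`, `positions`).
#' @export
synthesize_tap <- function(speed, array, params = tap_waveform_params(),
                           noise = noise_spec(), sample_rate = 50000,
                           duration = 6e-3, pre_roll = 1e-3,
                           noise_ref_amplitude = params$amplitude) {
  stopifnot(speed > 0, inherits(array, "sensor_array"),
            inherits(noise, "noise_spec"), pre_roll >= 0)
  if (sample_rate <= 2 * noise$band[2]) {
    stop("sample_rate must exceed twice the noise band's upper cutoff",
         call. = FALSE)
  }
  n <- round(duration * sample_rate)
  onset <- round(pre_roll * sample_rate) + 1L
  pos <- array$positions
  arrivals <- pos / speed
  if (max(arrivals) >= duration - pre_roll) {
    stop(sprintf("wave arrival %.3f ms exceeds the %.3f ms post-onset window",
                 max(arrivals) * 1000, (duration - pre_roll) * 1000),
         call. = FALSE)
  }
  wn <- 2 * pi * params$natural_frequency
  zeta <- params$damping_ratio
  gain <- .sdof_gain(wn, zeta, params$amplitude)
  t <- (seq_len(n) - onset) / sample_rate
  noise_sd <- if (is.infinite(noise$snr)) 0 else noise_ref_amplitude / noise$snr
  samples <- matrix(0, nrow = n, ncol = length(pos))
  for (i in seq_along(pos)) {
    ch <- .sdof_impulse_kernel(t - arrivals[i], wn, zeta, gain)
    if (noise_sd > 0) {
      ch <- ch + band_limited_noise(n, noise_sd, noise$band, sample_rate)
    }
    samples[, i] <- ch
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 tap_onset = onset,
                 truth = list(speed = speed, arrivals = arrivals,
                              positions = pos, waveform = params)),
            class = "tap_recording")
}

#' @export
print.tap_recording <- function(x, ...) {
  cat(sprintf("<tap_recording> %d channels x %d samples @ %g kHz%s\n",
              ncol(x$samples), nrow(x$samples), x$sample_rate / 1000,
              if (!is.null(x$truth)) sprintf(" (truth: %.1f m/s)",
                                             x$truth$speed) else ""))
  invisible(x)
}

#' Perturb sensor positions
#'
#' Adds independent Gaussian offsets (SD `sd` meters) to each position,
#' emulating imprecise sensor placement. Offsets are redrawn until the array
#' ordering is preserved.
#'
#' @param array A [sensor_array()].
#' @param sd Offset SD, meters (>= 0).
#' @return A new `sensor_array`.
#' @export
perturb_positions <- function(array, sd) {
  stopifnot(inherits(array, "sensor_array"), sd >= 0)
  if (sd == 0) return(array)
  pos <- array$positions
  repeat {
    p <- pos + stats::rnorm(length(pos), 0, sd)
    if (all(p > 0) && all(diff(p) > 0)) return(sensor_array(p))
  }
}

#' Simulate one stride of tensiometer taps
#'
#' Generates `round(stride_duration * tap_rate)` taps. Tap `k` occurs at gait
#' fraction `(k - 1) / n_taps`; its true speed is the profile evaluated there,
#' its waveform parameters are drawn from their between-tap normal
#' distributions, its amplitude is the nominal amplitude times the profile's
#' envelope, and its noise realization is independent of every other tap.
#'
#' Noise scales with the tap's local amplitude, so the prescribed SNR holds
#' tap by tap across the stride.
#'
#' @param profile A [make_gait_profile()] result.
#' @param array A [sensor_array()] (the true, possibly perturbed, geometry).
#' @param params A [tap_waveform_params()] holding nominal values and SDs.
#' @param noise A [noise_spec()].
#' @param tap_rate Tapper rate, Hz.
#' @param stride_duration Stride duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Record length per tap, seconds.
#' @return A `stride_simulation`: list with `taps` (list of `tap_recording`),
#'   `tap_rate`, `gait_fraction` (per tap), `profile`, `array`.
#' @export
simulate_stride <- function(profile, array, params = tap_waveform_params(),
                            noise = noise_spec(), tap_rate = 100,
                            stride_duration = 1.1, sample_rate = 50000,
                            duration = 6e-3) {
  stopifnot(inherits(profile, "gait_profile"), tap_rate > 0,
            stride_duration > 0)
  n_taps <- round(stride_duration * tap_rate)
  frac <- (seq_len(n_taps) - 1) / n_taps
  speeds <- profile$speed(frac)
  envs <- profile$envelope(frac)
  taps <- vector("list", n_taps)
  for (k in seq_len(n_taps)) {
    fn <- stats::rnorm(1, params$natural_frequency, params$frequency_sd)
    zt <- stats::rnorm(1, params$damping_ratio, params$damping_sd)
    # keep the response physical/underdamped even in distribution tails
    fn <- max(fn, 100)
    zt <- min(max(zt, 0.02), 0.98)
    pk <- tap_waveform_params(fn, zt, params$amplitude * envs[k],
                              frequency_sd = 0, damping_sd = 0)
    taps[[k]] <- synthesize_tap(speeds[k], array, pk, noise,
                                sample_rate = sample_rate, duration = duration)
  }
  structure(list(taps = taps, tap_rate = tap_rate, gait_fraction = frac,
                 profile = profile, array = array),
            class = "stride_simulation")
}

#' @export
print.stride_simulation <- function(x, ...) {
  cat(sprintf("<stride_simulation> %d taps @ %g Hz, %d channels, profile '%s'\n",
              length(x$taps), x$tap_rate, ncol(x$taps[[1]]$samples),
              x$profile$kind))
  invisible(x)
}
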