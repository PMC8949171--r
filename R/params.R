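#' Tap waveform parameters
#'
#' Parameters of the underdamped second-order impulse response used to model
#' the tapper-induced shear wave as sensed by an accelerometer. Nominal values
#' follow bench characterization of tendon tensiometers: natural frequency
#' 1600 Hz (between-tap SD 100 Hz), damping ratio 0.5 (SD 0.05), peak
#' acceleration 20 m/s^2.
#'
#' @param natural_frequency Undamped natural frequency, Hz.
#' @param damping_ratio Dimensionless damping ratio, strictly in (0, 1).
#' @param amplitude Peak absolute acceleration of the response, m/s^2.
#' @param frequency_sd Between-tap SD of the natural frequency, Hz.
#' @param damping_sd Between-tap SD of the damping ratio.
#' @return An object of class `tap_waveform_params`.
#' @export
#' @examples
#' tap_waveform_params()
tap_waveform_params <- function(natural_frequency = 1600, damping_ratio = 0.5,
                                amplitude = 20, frequency_sd = 100,
                                damping_sd = 0.05) {
  stopifnot(natural_frequency > 0, amplitude > 0,
            frequency_sd >= 0, damping_sd >= 0)
  if (damping_ratio <= 0 || damping_ratio >= 1) {
    stop("damping_ratio must lie strictly in (0, 1): the response must be underdamped",
         call. = FALSE)
  }
  structure(list(natural_frequency = natural_frequency,
                 damping_ratio = damping_ratio,
                 amplitude = amplitude,
                 frequency_sd = frequency_sd,
                 damping_sd = damping_sd),
            class = "tap_waveform_params")
}

#' Accelerometer array geometry
#'
#' Ordered tapper-to-accelerometer distances. The default is the four-sensor
#' layout at 15/25/35/45 mm from the excitation.
#'
#' @param positions Numeric vector of distances from the tapper, meters,
#'   strictly increasing, all positive, length >= 2.
#' @return An object of class `sensor_array`.
#' @export
#' @examples
#' sensor_array()                     # 4 sensors
#' sensor_array(c(0.015, 0.025))      # 2 sensors
sensor_array <- function(positions = c(0.015, 0.025, 0.035, 0.045)) {
  positions <- as.numeric(positions)
  stopifnot(length(positions) >= 2, all(positions > 0))
  if (any(diff(positions) <= 0)) {
    stop("sensor positions must be strictly increasing", call. = FALSE)
  }
  structure(list(positions = positions), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d accelerometers at [%s] mm from tapper\n",
              length(x$positions),
              paste(format(x$positions * 1000), collapse = ", ")))
  invisible(x)
}

#' Sensor noise specification
#'
#' Band-limited Gaussian sensor noise. SNR is defined as the nominal peak
#' signal amplitude divided by the noise standard deviation, so `snr = 2`
#' means the noise SD equals half the signal amplitude; `snr = Inf` disables
#' noise.
#'
#' @param snr Signal-to-noise ratio (> 0, `Inf` allowed).
#' @param band Length-2 numeric, pass-band cutoffs in Hz (low, high).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr = Inf, band = c(100, 5000)) {
  stopifnot(length(band) == 2, is.numeric(snr), length(snr) == 1)
  if (!(snr > 0)) stop("snr must be positive (Inf allowed)", call. = FALSE)
  if (!(band[1] > 0 && band[2] > band[1])) {
    stop("noise band must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(snr = snr, band = as.numeric(band)), class = "noise_spec")
}

#' Cross-correlation window specification
#'
#' @param template_length Template window length, seconds; valid range 1-3 ms.
#' @param delta_search Half-width of the tap-to-tap arrival-change search,
#'   seconds.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(template_length = 2e-3, delta_search = 5e-4) {
  if (template_length < 1e-3 || template_length > 3e-3) {
    stop("template_length must lie in [1, 3] ms", call. = FALSE)
  }
  stopifnot(delta_search > 0)
  structure(list(template_length = template_length, delta_search = delta_search),
            class = "window_spec")
}
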