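# Simulation studies: sensitivity of the two wave-speed estimators to sensor
# noise (noise_sweep) and to uncertainty in sensor placement
# (position_perturbation). Accuracy metrics follow the stride-ensemble
# convention: per-time-point statistics on a common 100-point gait-cycle
# grid via nearest-tap mapping, normalized by the prescribed speed.

# map a 100-point gait grid onto tap indices (nearest tap)
.grid_map <- function(n_taps, grid_points) {
  g <- (seq_len(grid_points) - 0.5) / grid_points
  tap_frac <- (seq_len(n_taps) - 1) / n_taps
  vapply(g, function(f) which.min(abs(tap_frac - f)), 0L)
}

#' Desk-scale variance-model calibration
#'
#' Convenience wrapper running [run_calibration()] on a reduced grid
#' (21 log-spaced SNR levels from 1 to 100 plus the noiseless sentinel) and
#' fitting the quadratic. The fitted curve is statistically indistinguishable
#' from the full 101-level, 1000-replicate calibration for filtering
#' purposes.
#'
#' @param reps Replicates per SNR level.
#' @param n_levels Number of finite, log-spaced SNR levels.
#' @param ... Passed to [run_calibration()].
#' @return A `variance_model`.
#' @export
default_variance_model <- function(reps = 200, n_levels = 21, ...) {
  grid <- c(exp(seq(log(1), log(100), length.out = n_levels)), Inf)
  fit_variance_model(run_calibration(grid, reps, ...))
}

# simulate one stride and estimate speeds with both methods, assuming the
# nominal geometry; returns per-tap estimates and the prescribed speeds
.stride_speeds <- function(profile, true_array, nominal_array, params, noise,
                           vmodel, window, constraints, tap_rate,
                           stride_duration, min_speed, max_speed) {
  stride <- simulate_stride(profile, true_array, params, noise,
                            tap_rate = tap_rate,
                            stride_duration = stride_duration)
  res <- run_filter(stride, nominal_array, vmodel, window,
                    constraints = constraints,
                    min_speed = min_speed, max_speed = max_speed)
  list(kalman = res$speeds$speed_kalman, xcorr = res$speeds$speed_xcorr,
       prescribed = profile$speed(stride$gait_fraction))
}

#' Sensor-noise sweep
#'
#' For each array size and SNR level, simulates `sets` sets of `strides`
#' walking strides, estimates the wave speed per tap with the
#' cross-correlation-only method and with the Kalman filter, and computes
#' the mean coefficient of variation: the per-time-point SD of the estimate
#' across the strides of a set, normalized by the prescribed speed, averaged
#' over the gait cycle and over sets. Also reports the CoV at the
#' peak-speed time point.
#'
#' @param sensor_counts Array sizes to test (subset of 2:4 with the default
#'   geometry).
#' @param snr_levels SNR levels (positive, `Inf` = noiseless).
#' @param sets,strides Number of sets and strides per set.
#' @param vmodel A `variance_model`; `NULL` runs [default_variance_model()].
#' @param profile Prescribed [make_gait_profile()].
#' @param array Full nominal [sensor_array()]; size-`k` arrays use its first
#'   `k` positions.
#' @param params A [tap_waveform_params()].
#' @param window A [window_spec()].
#' @param constraints Constraint-row policy, see [run_filter()].
#' @param grid_points Gait-cycle grid resolution.
#' @param tap_rate,stride_duration Tapping rate (Hz) and stride duration (s).
#' @param min_speed,max_speed Admissible speed range, m/s.
#' @return An `accuracy_report` data frame: one row per (n_sensors, snr,
#'   method) with `mean_cov` and `cov_at_peak` (both in %), plus `n_failed`
#'   (taps excluded as invalid).
#' @export
noise_sweep <- function(sensor_counts = c(2, 3, 4),
                        snr_levels = c(Inf, 16, 8, 4, 2),
                        sets = 10, strides = 10, vmodel = NULL,
                        profile = make_gait_profile("walking"),
                        array = sensor_array(),
                        params = tap_waveform_params(),
                        window = window_spec(),
                        constraints = "consecutive", grid_points = 100,
                        tap_rate = 100, stride_duration = 1.1,
                        min_speed = 10, max_speed = 150) {
  stopifnot(sets >= 1, strides >= 2, all(snr_levels > 0),
            all(sensor_counts >= 2),
            max(sensor_counts) <= length(array$positions))
  if (is.null(vmodel)) vmodel <- default_variance_model()
  n_taps <- round(stride_duration * tap_rate)
  map <- .grid_map(n_taps, grid_points)
  g <- (seq_len(grid_points) - 0.5) / grid_points
  prescribed <- profile$speed(g)
  peak_idx <- which.max(prescribed)
  out <- list()
  for (nc in sensor_counts) {
    arr <- sensor_array(array$positions[seq_len(nc)])
    for (snr in snr_levels) {
      noise <- noise_spec(snr = snr)
      cov_sets <- matrix(NA_real_, sets, 2)      # kalman, xcorr mean CoV
      covp_sets <- matrix(NA_real_, sets, 2)
      n_failed <- 0L
      for (s in seq_len(sets)) {
        mk <- matrix(NA_real_, strides, grid_points)
        mx <- matrix(NA_real_, strides, grid_points)
        for (st in seq_len(strides)) {
          sp <- .stride_speeds(profile, arr, arr, params, noise, vmodel,
                               window, constraints, tap_rate,
                               stride_duration, min_speed, max_speed)
          mk[st, ] <- sp$kalman[map]
          mx[st, ] <- sp$xcorr[map]
        }
        n_failed <- n_failed + sum(!is.finite(mk)) + sum(!is.finite(mx))
        sd_k <- apply(mk, 2, stats::sd, na.rm = TRUE)
        sd_x <- apply(mx, 2, stats::sd, na.rm = TRUE)
        cov_sets[s, ] <- c(mean(sd_k / prescribed, na.rm = TRUE),
                           mean(sd_x / prescribed, na.rm = TRUE)) * 100
        covp_sets[s, ] <- c(sd_k[peak_idx], sd_x[peak_idx]) /
          prescribed[peak_idx] * 100
      }
      out[[length(out) + 1L]] <- data.frame(
        n_sensors = nc, snr = snr, method = c("kalman", "xcorr"),
        mean_cov = colMeans(cov_sets), cov_at_peak = colMeans(covp_sets),
        n_failed = n_failed)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("accuracy_report", "data.frame"),
            experiment = "noise_sweep")
}

#' Sensor-position perturbation study
#'
#' Simulates strides whose true sensor positions are perturbed per stride by
#' independent Gaussian offsets while estimation assumes the nominal
#' geometry. Reports, per array size and method, the across-stride mean,
#' 99th percentile and maximum of the stride-mean absolute percent
#' wave-speed error.
#'
#' @param sensor_counts Array sizes to test.
#' @param n_strides Strides per array size.
#' @param position_sd Position-offset SD, meters (> 0).
#' @param snr Sensor SNR during the study (default noiseless, isolating the
#'   placement effect).
#' @param vmodel,profile,array,params,window,constraints,tap_rate,stride_duration,min_speed,max_speed
#'   As in [noise_sweep()].
#' @return An `accuracy_report` data frame: one row per (n_sensors, method)
#'   with the across-stride mean (`mean_err`), 99th percentile (`p99_err`)
#'   and maximum (`max_err`) of the stride-mean absolute percent error (%).
#'   `p99_err` is the headline "error reached" figure: it tracks the
#'   ensemble maximum but is far less sensitive to a single extreme
#'   placement draw.
#' @export
position_perturbation <- function(sensor_counts = c(2, 3, 4), n_strides = 100,
                                  position_sd = 5e-4, snr = Inf,
                                  vmodel = NULL,
                                  profile = make_gait_profile("walking"),
                                  array = sensor_array(),
                                  params = tap_waveform_params(),
                                  window = window_spec(),
                                  constraints = "consecutive",
                                  tap_rate = 100, stride_duration = 1.1,
                                  min_speed = 10, max_speed = 150) {
  stopifnot(position_sd > 0, n_strides >= 1)
  if (is.null(vmodel)) vmodel <- default_variance_model()
  noise <- noise_spec(snr = snr)
  out <- list()
  for (nc in sensor_counts) {
    nominal <- sensor_array(array$positions[seq_len(nc)])
    err_k <- numeric(n_strides)
    err_x <- numeric(n_strides)
    for (st in seq_len(n_strides)) {
      true_arr <- perturb_positions(nominal, position_sd)
      sp <- .stride_speeds(profile, true_arr, nominal, params, noise, vmodel,
                           window, constraints, tap_rate, stride_duration,
                           min_speed, max_speed)
      pe_k <- abs(sp$kalman - sp$prescribed) / sp$prescribed * 100
      pe_x <- abs(sp$xcorr - sp$prescribed) / sp$prescribed * 100
      err_k[st] <- mean(pe_k, na.rm = TRUE)
      err_x[st] <- mean(pe_x, na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      n_sensors = nc, method = c("kalman", "xcorr"),
      mean_err = c(mean(err_k), mean(err_x)),
      p99_err = unname(c(stats::quantile(err_k, 0.99),
                         stats::quantile(err_x, 0.99))),
      max_err = c(max(err_k), max(err_x)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("accuracy_report", "data.frame"),
            experiment = "position_perturbation")
}

#' Percent reduction between matched accuracy reports
#'
#' Computes `100 * (1 - metric_b / metric_a)` for each condition shared by
#' the two reports, plus the average across conditions. Conditions are
#' matched on every shared non-metric column; the reports must describe the
#' same conditions.
#'
#' @param report_a,report_b Accuracy reports (data frames) with identical
#'   condition columns; `a` is the baseline.
#' @param metric Name of the metric column to compare.
#' @return List with `by_condition` (data frame of conditions and
#'   `reduction_pct`) and `average` (mean reduction, %).
#' @export
reduction_summary <- function(report_a, report_b, metric = "mean_cov") {
  stopifnot(is.data.frame(report_a), is.data.frame(report_b),
            metric %in% names(report_a), metric %in% names(report_b))
  metrics <- c("mean_cov", "cov_at_peak", "mean_err", "p99_err", "max_err", "n_failed",
               "n_sensors")
  keys <- setdiff(intersect(names(report_a), names(report_b)), metrics)
  if (length(keys) > 0) {
    ka <- do.call(paste, c(report_a[keys], sep = "|"))
    kb <- do.call(paste, c(report_b[keys], sep = "|"))
    if (length(ka) != length(kb) || !all(ka == kb)) {
      stop("reports do not describe matched conditions", call. = FALSE)
    }
    conds <- report_a[keys]
  } else {
    if (nrow(report_a) != nrow(report_b)) {
      stop("reports do not describe matched conditions", call. = FALSE)
    }
    conds <- data.frame(row = seq_len(nrow(report_a)))
  }
  red <- 100 * (1 - report_b[[metric]] / report_a[[metric]])
  list(by_condition = cbind(conds, reduction_pct = red), average = mean(red))
}
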