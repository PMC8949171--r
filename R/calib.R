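# Monte-Carlo calibration of delay-estimate variance against correlation
# strength. The fitted quadratic r -> var(shift) supplies the Kalman process
# (Q) and measurement (R) noise covariances at run time.

#' Default calibration SNR grid
#'
#' 100 log-spaced SNR values from 1 to 100 plus the noiseless sentinel
#' (`Inf`), 101 levels in total.
#'
#' @return Numeric vector of length 101.
#' @export
default_snr_grid <- function() {
  c(exp(seq(log(1), log(100), length.out = 100)), Inf)
}

# one simulated tap pair sharing a waveform realization: template record and
# a search record whose arrival is offset by true_shift
.calibration_pair <- function(snr, params, true_shift, t0, n, fs, band) {
  fn <- stats::rnorm(1, params$natural_frequency, params$frequency_sd)
  zt <- stats::rnorm(1, params$damping_ratio, params$damping_sd)
  fn <- max(fn, 100)
  zt <- min(max(zt, 0.02), 0.98)
  wn <- 2 * pi * fn
  gain <- .sdof_gain(wn, zt, params$amplitude)
  t <- seq(0, by = 1 / fs, length.out = n)
  s1 <- .sdof_impulse_kernel(t - t0, wn, zt, gain)
  s2 <- .sdof_impulse_kernel(t - t0 - true_shift, wn, zt, gain)
  if (is.finite(snr)) {
    sd <- params$amplitude / snr
    s1 <- s1 + band_limited_noise(n, sd, band, fs)
    s2 <- s2 + band_limited_noise(n, sd, band, fs)
  }
  rec <- function(x) structure(list(samples = matrix(x, ncol = 1),
                                    sample_rate = fs, tap_onset = 1L,
                                    truth = NULL),
                               class = "tap_recording")
  list(prev = rec(s1), curr = rec(s2))
}

#' Monte-Carlo calibration of delay variance versus correlation
#'
#' For each SNR level, simulates `reps` tap pairs with a fixed known arrival
#' shift, runs the cross-correlation delay estimator on each, and records the
#' mean peak correlation and the empirical variance of the estimated shift.
#' Each pair shares one waveform realization (parameters drawn fresh per
#' event) and carries independent noise on the two records.
#'
#' @param snr_grid SNR levels (positive, `Inf` = noiseless). Default:
#'   [default_snr_grid()].
#' @param reps Replicates per level (>= 2). Default 1000, giving the default
#'   grid 101,000 simulated events.
#' @param params A [tap_waveform_params()].
#' @param window A [window_spec()].
#' @param true_shift Known arrival shift between the pair, seconds. Default:
#'   0 for `"delta"` style; 0.2 ms (mid-range of the admissible travel
#'   times) for `"tau"` style, whose search excludes non-positive shifts.
#' @param style `"delta"` (windows centred on the known arrival, short
#'   search; the tap-to-tap configuration) or `"tau"` (template anchored at
#'   tap onset with a travel-time-sized search; the inter-sensor
#'   configuration).
#' @param sample_rate Sampling rate, Hz.
#' @param band Noise band, Hz.
#' @return A `calibration_table`: data frame with columns `snr`, `mean_r`,
#'   `var_shift` (s^2), `n_ok`; rows where more than half the replicates
#'   failed are dropped with a warning.
#' @export
run_calibration <- function(snr_grid = default_snr_grid(), reps = 1000,
                            params = tap_waveform_params(),
                            window = window_spec(), true_shift = NULL,
                            style = c("delta", "tau"), sample_rate = 50000,
                            band = c(100, 5000)) {
  style <- match.arg(style)
  if (is.null(true_shift)) true_shift <- if (style == "tau") 2e-4 else 0
  stopifnot(reps >= 2, length(snr_grid) >= 1, all(snr_grid > 0))
  fs <- sample_rate
  t0 <- 1.5e-3
  n <- round(4.5e-3 * fs) + round(abs(true_shift) * fs)
  rows <- lapply(snr_grid, function(snr) {
    shifts <- numeric(reps)
    rs <- numeric(reps)
    ok <- logical(reps)
    for (k in seq_len(reps)) {
      pair <- .calibration_pair(snr, params, true_shift, t0, n, fs, band)
      m <- tryCatch({
        if (style == "delta") {
          estimate_arrival_delta(pair$prev, pair$curr, 1L, window,
                                 prev_arrival = t0)
        } else {
          arr <- sensor_array(c(1e-3, 1e-3 + 0.01))  # 10 mm virtual spacing
          rec <- pair$prev
          rec$samples <- cbind(pair$prev$samples[, 1], pair$curr$samples[, 1])
          estimate_travel_time(rec, 1L, 2L, arr, window)
        }
      }, error = function(e) NULL)
      if (!is.null(m)) {
        shifts[k] <- m$shift
        rs[k] <- m$r
        ok[k] <- TRUE
      }
    }
    if (mean(ok) <= 0.5) return(NULL)
    data.frame(snr = snr, mean_r = mean(rs[ok]),
               var_shift = stats::var(shifts[ok]), n_ok = sum(ok))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0) {
    warning(sprintf("%d SNR level(s) dropped (more than 50%% estimator failures)",
                    dropped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("calibration produced no usable rows")
  structure(out, class = c("calibration_table", "data.frame"),
            style = style, true_shift = true_shift)
}

#' Fit the quadratic variance-versus-correlation model
#'
#' Least-squares quadratic of the per-level shift variance on the per-level
#' mean correlation coefficient. The variance floor is the smallest positive
#' observed variance, so downstream noise covariances stay on the scale the
#' estimator can actually achieve.
#'
#' @param table A `calibration_table` (or data frame with `mean_r`,
#'   `var_shift`), at least 3 rows.
#' @return A `variance_model`: list with `coefficients` (intercept, linear,
#'   quadratic), `r_range`, `variance_floor`, `r_squared`.
#' @export
fit_variance_model <- function(table) {
  stopifnot(is.data.frame(table), all(c("mean_r", "var_shift") %in% names(table)))
  if (nrow(table) < 3) stop("need at least 3 calibration rows", call. = FALSE)
  fit <- stats::lm(var_shift ~ mean_r + I(mean_r^2), data = table)
  cf <- unname(stats::coef(fit))
  if (anyNA(cf)) stop("rank-deficient quadratic fit", call. = FALSE)
  # floor at the smallest positive observed variance: the noiseless row can
  # be exactly zero (the estimator is exact there), which would make
  # downstream noise covariances degenerate
  pos <- table$var_shift[table$var_shift > 0]
  floor_v <- if (length(pos) > 0) min(pos) else 1e-16
  structure(list(coefficients = cf,
                 r_range = range(table$mean_r),
                 variance_floor = floor_v,
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf(paste0("<variance_model> var = %.3e %+.3e r %+.3e r^2 on ",
                     "r in [%.4f, %.4f]\n  floor %.3e s^2, R^2 = %.3f\n"),
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$r_range[1], x$r_range[2], x$variance_floor, x$r_squared))
  invisible(x)
}

#' Delay-estimate variance predicted from correlation strength
#'
#' Evaluates the calibrated quadratic at `r`, with `r` clipped to the fitted
#' range (no extrapolation) and additionally to the quadratic's vertex when
#' the parabola opens upward, so the prediction is non-increasing in `r`;
#' the result is floored at the model's variance floor. Total on `[-1, 1]`.
#'
#' @param model A [fit_variance_model()] result.
#' @param r Correlation coefficient(s).
#' @return Predicted variance(s) of the delay estimate, s^2.
#' @export
variance_from_r <- function(model, r) {
  stopifnot(inherits(model, "variance_model"))
  .variance_fn(model)(r)
}

# precompute the clipped-quadratic evaluator once (used per filter step)
.variance_fn <- function(model) {
  cf <- model$coefficients
  lo <- model$r_range[1]
  hi <- model$r_range[2]
  if (cf[3] > 0) {
    vertex <- -cf[2] / (2 * cf[3])
    if (vertex < hi) hi <- max(vertex, lo)
  }
  floor_v <- model$variance_floor
  function(r) {
    rc <- pmin(pmax(r, lo), hi)
    pmax(cf[1] + cf[2] * rc + cf[3] * rc^2, floor_v)
  }
}

#' Write / read a variance model as YAML
#'
#' @param model A `variance_model`.
#' @param path File path.
#' @return `write_variance_model` returns `path` invisibly;
#'   `read_variance_model` returns the restored `variance_model`.
#' @export
write_variance_model <- function(model, path) {
  stopifnot(inherits(model, "variance_model"))
  yaml::write_yaml(list(coefficients = model$coefficients,
                        r_range = model$r_range,
                        variance_floor = model$variance_floor,
                        r_squared = model$r_squared), path)
  invisible(path)
}

#' @rdname write_variance_model
#' @export
read_variance_model <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("coefficients", "r_range", "variance_floor")
  if (!all(need %in% names(x))) {
    stop("not a variance model file: missing ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  structure(list(coefficients = as.numeric(x$coefficients),
                 r_range = as.numeric(x$r_range),
                 variance_floor = as.numeric(x$variance_floor),
                 r_squared = if (is.null(x$r_squared)) NA_real_
                             else as.numeric(x$r_squared)),
            class = "variance_model")
}
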