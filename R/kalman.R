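# Kalman fusion of tensiometer delay measurements. State: the vector of wave
# arrival times T at each accelerometer. Control input: tap-to-tap arrival
# changes (delta-T). Observations: inter-sensor travel times (tau) plus
# optional constant-speed constraint rows tying arrival times to sensor
# positions. Wave speed is extracted per tap as the slope of a weighted
# least-squares regression of position on arrival time.

#' Build the Kalman model matrices for an accelerometer array
#'
#' State transition `F` and control matrix `B` are identity. The observation
#' matrix `H` stacks one travel-time row per consecutive sensor pair
#' (`-1` in column `i`, `+1` in column `j`) and one constant-speed constraint
#' row per requested pair (`+D_j` in column `i`, `-D_i` in column `j`,
#' asserting `D_j T_i - D_i T_j = 0`).
#'
#' @param array A [sensor_array()] (the assumed geometry).
#' @param constraint_pairs List of integer pairs `c(i, j)` to constrain, or
#'   `"consecutive"` (default) for all consecutive pairs, or `NULL` for none.
#' @return A `kalman_model`: list with `n`, `F`, `B`, `H`, `n_tau`,
#'   `constraint_pairs`, `positions`.
#' @export
#' @examples
#' build_kalman_model(sensor_array(c(0.015, 0.025, 0.035)))$H
build_kalman_model <- function(array, constraint_pairs = "consecutive") {
  stopifnot(inherits(array, "sensor_array"))
  pos <- array$positions
  n <- length(pos)
  if (identical(constraint_pairs, "consecutive")) {
    constraint_pairs <- lapply(seq_len(n - 1), function(i) c(i, i + 1L))
  }
  if (!is.null(constraint_pairs)) {
    key <- vapply(constraint_pairs, paste, "", collapse = "-")
    if (anyDuplicated(key)) stop("duplicate constraint pairs", call. = FALSE)
    bad <- vapply(constraint_pairs,
                  function(p) length(p) != 2 || p[1] >= p[2] || p[1] < 1 ||
                    p[2] > n, TRUE)
    if (any(bad)) stop("constraint pairs must be valid (i, j) with i < j",
                       call. = FALSE)
  }
  n_tau <- n - 1L
  m <- length(constraint_pairs)
  H <- matrix(0, n_tau + m, n)
  for (p in seq_len(n_tau)) {
    H[p, p] <- -1
    H[p, p + 1L] <- 1
  }
  for (q in seq_along(constraint_pairs)) {
    ij <- constraint_pairs[[q]]
    H[n_tau + q, ij[1]] <- pos[ij[2]]
    H[n_tau + q, ij[2]] <- -pos[ij[1]]
  }
  structure(list(n = n, F = diag(n), B = diag(n), H = H, n_tau = n_tau,
                 constraint_pairs = constraint_pairs, positions = pos),
            class = "kalman_model")
}

#' Kalman state: arrival times and their covariance
#'
#' @param T Arrival-time vector, seconds.
#' @param P Covariance matrix, s^2 (symmetric positive semidefinite).
#' @return A `kalman_state`.
#' @export
kalman_state <- function(T, P) {
  T <- as.numeric(T)
  P <- as.matrix(P)
  stopifnot(length(T) == nrow(P), nrow(P) == ncol(P))
  if (max(abs(P - t(P))) > 1e-12 * max(1, max(abs(P)))) {
    stop("P must be symmetric", call. = FALSE)
  }
  structure(list(T = T, P = (P + t(P)) / 2), class = "kalman_state")
}

#' @export
print.kalman_state <- function(x, ...) {
  cat("<kalman_state> T (us):", paste(sprintf("%.2f", x$T * 1e6), collapse = ", "),
      "\n  sd(T) (us):",
      paste(sprintf("%.3f", sqrt(diag(x$P)) * 1e6), collapse = ", "), "\n")
  invisible(x)
}

#' Kalman prediction step
#'
#' With identity `F` and `B`: `T <- T + delta_T`, `P <- P + Q`.
#'
#' @param state A [kalman_state()].
#' @param delta_T Control input: per-channel arrival changes, seconds.
#' @param Q Diagonal process covariance (vector of per-channel variances,
#'   s^2, all > 0).
#' @return The predicted `kalman_state`.
#' @export
kalman_predict <- function(state, delta_T, Q) {
  stopifnot(inherits(state, "kalman_state"),
            length(delta_T) == length(state$T), length(Q) == length(state$T))
  if (any(Q <= 0)) stop("process noise variances must be positive", call. = FALSE)
  kalman_state(state$T + delta_T, state$P + diag(Q, length(Q)))
}

#' Kalman measurement update
#'
#' Standard linear update with Joseph-form covariance for numerical symmetry:
#' innovation `y = z - H T`, `S = H P H' + R`, gain `K = P H' S^{-1}`,
#' `T <- T + K y`, `P <- (I - K H) P (I - K H)' + K R K'`.
#'
#' @param state A [kalman_state()] (the prior).
#' @param model A [build_kalman_model()] result.
#' @param z Observation vector: `n - 1` travel times then one zero per
#'   constraint row.
#' @param R Diagonal observation covariance (vector of variances, s^2 for tau
#'   rows, m^2 s^2 for constraint rows; all > 0).
#' @return The posterior `kalman_state`.
#' @export
kalman_update <- function(state, model, z, R) {
  stopifnot(inherits(state, "kalman_state"), inherits(model, "kalman_model"))
  H <- model$H
  if (length(z) != nrow(H) || length(R) != nrow(H)) {
    stop("z and R must have one entry per observation row", call. = FALSE)
  }
  if (any(R <= 0)) stop("observation variances must be positive", call. = FALSE)
  P <- state$P
  S <- H %*% P %*% t(H) + diag(R, length(R))
  K <- tryCatch(t(solve(S, H %*% P)),
                error = function(e) {
                  stop(sprintf("singular innovation covariance (rows %s)",
                               paste(seq_len(nrow(H)), collapse = ",")),
                       call. = FALSE)
                })
  Tn <- state$T + as.numeric(K %*% (z - H %*% state$T))
  IKH <- diag(model$n) - K %*% H
  Pn <- IKH %*% P %*% t(IKH) + K %*% diag(R, length(R)) %*% t(K)
  kalman_state(Tn, Pn)
}

#' Assemble one filter step's control input and observations
#'
#' Runs the delay estimators on a pair of consecutive taps: per-channel
#' arrival changes (templates centred on the previous state's arrival
#' estimates) populate the control input with `Q = variance_from_r(r)`;
#' per-consecutive-pair travel times populate the observation vector with
#' `R` from the same calibration; constraint rows observe zero with variance
#' `(D_i^2 + D_j^2) (sigma_pos / c_nominal)^2`, the Eq-residual variance
#' induced by independent per-sensor position errors of SD `sigma_pos`. A
#' degenerate estimator yields a zero shift whose variance is inflated 100x
#' rather than being dropped.
#'
#' @param prev_state The previous posterior [kalman_state()].
#' @param prev,curr Consecutive `tap_recording`s.
#' @param model A [build_kalman_model()] result.
#' @param window A [window_spec()].
#' @param vmodel A [fit_variance_model()] result.
#' @param position_sd Assumed sensor-position uncertainty, meters.
#' @param c_nominal Nominal wave speed for scaling the constraint variance,
#'   m/s.
#' @param min_speed,max_speed Admissible speed range for the tau search.
#' @return List with `delta_T`, `Q`, `z`, `R`, `r_delta`, `r_tau`,
#'   `flagged` (logical: any degraded row).
#' @export
assemble_step <- function(prev_state, prev, curr, model, window, vmodel,
                          position_sd = 5e-4, c_nominal = 50,
                          min_speed = 10, max_speed = 150) {
  n <- model$n
  arr <- sensor_array(model$positions)
  prior_arrivals <- prev_state$T
  vfr <- .variance_fn(vmodel)           # scalar fast path, hot loop
  delta_T <- numeric(n)
  Q <- numeric(n)
  r_delta <- numeric(n)
  flagged <- FALSE
  for (i in seq_len(n)) {
    m <- tryCatch(
      estimate_arrival_delta(prev, curr, i, window,
                             prev_arrival = prior_arrivals[i]),
      error = function(e) NULL)
    if (is.null(m)) {
      delta_T[i] <- 0
      Q[i] <- 100 * vfr(0)
      r_delta[i] <- NA_real_
      flagged <- TRUE
    } else {
      delta_T[i] <- m$shift
      Q[i] <- vfr(m$r)
      r_delta[i] <- m$r
      if (m$boundary) {
        Q[i] <- 100 * Q[i]
        flagged <- TRUE
      }
    }
  }
  n_tau <- model$n_tau
  z <- numeric(nrow(model$H))
  R <- numeric(nrow(model$H))
  r_tau <- numeric(n_tau)
  for (p in seq_len(n_tau)) {
    m <- tryCatch(
      estimate_travel_time(curr, p, p + 1L, arr, window, min_speed, max_speed,
                           template_anchor = prior_arrivals[p]),
      error = function(e) NULL)
    if (is.null(m)) {
      z[p] <- 0
      R[p] <- 100 * vfr(0)
      r_tau[p] <- NA_real_
      flagged <- TRUE
    } else {
      z[p] <- m$shift
      R[p] <- vfr(m$r)
      r_tau[p] <- m$r
      if (m$boundary) {
        R[p] <- 100 * R[p]
        flagged <- TRUE
      }
    }
  }
  for (q in seq_along(model$constraint_pairs)) {
    ij <- model$constraint_pairs[[q]]
    Dij2 <- sum(model$positions[ij]^2)
    R[n_tau + q] <- Dij2 * (position_sd / c_nominal)^2
  }
  list(delta_T = delta_T, Q = Q, z = z, R = R,
       r_delta = r_delta, r_tau = r_tau, flagged = flagged)
}

#' Wave speed from arrival times by weighted least squares
#'
#' Slope of sensor position (response) regressed on arrival time
#' (regressor), with intercept, weighted by the inverse posterior arrival
#' variances. The slope is the wave speed.
#'
#' @param array A [sensor_array()] (assumed geometry).
#' @param state A [kalman_state()], or a list with `T` and `P`.
#' @param weights Optional explicit weights (default `1 / diag(P)`).
#' @return A `speed_estimate`: list with `speed` (m/s), `se`, `weights`,
#'   `method = "kalman"`.
#' @export
speed_from_arrivals <- function(array, state, weights = NULL) {
  stopifnot(inherits(array, "sensor_array"))
  D <- array$positions
  T <- state$T
  if (is.null(weights)) weights <- 1 / diag(state$P)
  stopifnot(length(T) == length(D), all(weights >= 0), any(weights > 0))
  w <- weights / sum(weights)
  Tb <- sum(w * T)
  Db <- sum(w * D)
  sxx <- sum(w * (T - Tb)^2)
  if (sxx <= 0) stop("zero arrival-time spread: speed undefined", call. = FALSE)
  slope <- sum(w * (T - Tb) * (D - Db)) / sxx
  resid <- D - Db - slope * (T - Tb)
  dof <- max(length(D) - 2, 1)
  se <- sqrt(sum(w * resid^2) / dof / sxx)
  structure(list(speed = slope, se = se, weights = weights,
                 method = "kalman"),
            class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("<speed_estimate> %.2f m/s (se %.2f, %s)\n",
              x$speed, x$se, x$method))
  invisible(x)
}

#' Cross-correlation-only wave speed for one tap
#'
#' The traditional estimator: with two sensors, `speed = spacing / tau`; with
#' more, arrival times are accumulated from consecutive-pair travel times
#' (first sensor as reference) and the speed is the unweighted least-squares
#' slope of position on arrival time. Each pair's template is centred on the
#' proximal channel's absolute peak so the wave stays in-window across the
#' whole speed range.
#'
#' @param rec A `tap_recording`.
#' @param array The assumed [sensor_array()].
#' @param window A [window_spec()].
#' @param min_speed,max_speed Admissible speed range for the tau search.
#' @return A `speed_estimate` with `method = "xcorr"` and fields `taus`,
#'   `rs`, `invalid` (TRUE when any tau <= 0).
#' @export
xcorr_only_speed <- function(rec, array, window = window_spec(),
                             min_speed = 10, max_speed = 150) {
  n <- length(array$positions)
  taus <- numeric(n - 1)
  rs <- numeric(n - 1)
  fs <- rec$sample_rate
  for (p in seq_len(n - 1)) {
    anchor <- (which.max(abs(rec$samples[, p])) - rec$tap_onset) / fs
    m <- estimate_travel_time(rec, p, p + 1L, array, window,
                              min_speed, max_speed,
                              template_anchor = anchor)
    taus[p] <- m$shift
    rs[p] <- m$r
  }
  sp <- .xcorr_speed_from_taus(array$positions, taus)
  structure(list(speed = sp$speed, se = sp$se, taus = taus, rs = rs,
                 invalid = sp$invalid, method = "xcorr"),
            class = "speed_estimate")
}

# speed from consecutive-pair travel times: two-point ratio for n = 2,
# unweighted LS slope of position on accumulated arrivals for n > 2
.xcorr_speed_from_taus <- function(positions, taus) {
  n <- length(positions)
  invalid <- any(taus <= 0)
  arrivals <- c(0, cumsum(taus))
  if (n == 2) {
    speed <- if (taus[1] > 0) diff(positions) / taus[1] else NA_real_
    se <- NA_real_
  } else {
    fit <- stats::lm.fit(cbind(1, arrivals), positions)
    speed <- unname(fit$coefficients[2])
    sxx <- sum((arrivals - mean(arrivals))^2)
    se <- sqrt(sum(fit$residuals^2) / max(n - 2, 1) / sxx)
  }
  list(speed = speed, se = se, invalid = invalid)
}

# initial state from the first tap: arrivals anchored at T1 = D1 / c_xcorr,
# accumulated along consecutive-pair travel times; P0 = 10x the calibrated
# variance of those measurements
.initial_state <- function(rec, array, window, vmodel, min_speed, max_speed) {
  xc <- xcorr_only_speed(rec, array, window, min_speed, max_speed)
  c0 <- xc$speed
  if (!is.finite(c0) || c0 <= 0) c0 <- 50
  T0 <- array$positions[1] / c0 + c(0, cumsum(xc$taus))
  v <- 10 * variance_from_r(vmodel, c(xc$rs[1], xc$rs))
  list(state = kalman_state(T0, diag(v, length(v))), xc = xc)
}

#' Run the Kalman filter over a tap sequence
#'
#' Initializes the state from the first tap's travel times (anchored at
#' `T_1 = D_1 / c_xcorr`), then for each subsequent tap assembles the
#' control input and observations, predicts, updates, and extracts the
#' weighted least-squares speed. The cross-correlation-only speed is
#' computed for every tap as the comparison baseline.
#'
#' @param taps A `stride_simulation` or list of `tap_recording`s (>= 2).
#' @param array The assumed [sensor_array()] geometry.
#' @param vmodel A [fit_variance_model()] result.
#' @param window A [window_spec()].
#' @param constraints `"consecutive"` (default), `NULL` to disable, or an
#'   explicit pair list (see [build_kalman_model()]).
#' @param position_sd Assumed sensor-position uncertainty for constraint
#'   rows, meters.
#' @param min_speed,max_speed Admissible wave-speed range, m/s.
#' @return A `filter_result`: list with `speeds` (data frame: `tap`,
#'   `speed_kalman`, `speed_xcorr`, `se_kalman`, `flagged`), `states`
#'   (list of per-tap posteriors), `model`.
#' @export
run_filter <- function(taps, array, vmodel, window = window_spec(),
                       constraints = "consecutive", position_sd = 5e-4,
                       min_speed = 10, max_speed = 150) {
  if (inherits(taps, "stride_simulation")) taps <- taps$taps
  stopifnot(length(taps) >= 2, inherits(array, "sensor_array"))
  model <- build_kalman_model(array, constraints)
  n_taps <- length(taps)
  init <- .initial_state(taps[[1]], array, window, vmodel, min_speed, max_speed)
  state <- init$state
  speed_k <- numeric(n_taps)
  speed_x <- numeric(n_taps)
  se_k <- numeric(n_taps)
  flagged <- logical(n_taps)
  states <- vector("list", n_taps)
  speed_k[1] <- init$xc$speed        # first tap: no delta-T yet
  speed_x[1] <- init$xc$speed
  se_k[1] <- NA_real_
  states[[1]] <- state
  c_nom <- if (is.finite(init$xc$speed) && init$xc$speed > 0)
    init$xc$speed else 50
  for (k in 2:n_taps) {
    step <- assemble_step(state, taps[[k - 1]], taps[[k]], model, window,
                          vmodel, position_sd = position_sd,
                          c_nominal = c_nom, min_speed = min_speed,
                          max_speed = max_speed)
    state <- kalman_predict(state, step$delta_T, step$Q)
    state <- kalman_update(state, model, step$z, step$R)
    est <- speed_from_arrivals(array, state)
    # the cross-correlation baseline reuses this tap's tau measurements
    xc <- .xcorr_speed_from_taus(array$positions,
                                 step$z[seq_len(model$n_tau)])
    speed_k[k] <- est$speed
    speed_x[k] <- xc$speed
    se_k[k] <- est$se
    flagged[k] <- step$flagged
    states[[k]] <- state
    if (is.finite(est$speed) && est$speed > 0) c_nom <- est$speed
  }
  structure(list(speeds = data.frame(tap = seq_len(n_taps),
                                     speed_kalman = speed_k,
                                     speed_xcorr = speed_x,
                                     se_kalman = se_k, flagged = flagged),
                 states = states, model = model),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d taps, %d sensors; mean speed %.2f m/s (kalman), %.2f m/s (xcorr)\n",
              nrow(x$speeds), x$model$n,
              mean(x$speeds$speed_kalman, na.rm = TRUE),
              mean(x$speeds$speed_xcorr, na.rm = TRUE)))
  invisible(x)
}
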