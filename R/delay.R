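# Time-delay estimation by normalized cross-correlation with sub-sample
# cosine interpolation. Two estimators share the machinery: inter-sensor
# wave travel time (tau, spatial) and tap-to-tap arrival change (delta-T,
# temporal).

#' Normalized cross-correlation over integer lags
#'
#' Pearson correlation between `template` and every `length(template)`-sample
#' window of `search`, one value per integer lag `0 .. length(search) -
#' length(template)`. Search windows with zero variance return `r = 0` (no
#' shape to match); a zero-variance template is an error.
#'
#' @param template Numeric template waveform.
#' @param search Numeric search waveform, at least as long as the template.
#' @return Numeric vector of correlations in `[-1, 1]`.
#' @export
normalized_xcorr <- function(template, search) {
  .ncc_kernel(as.numeric(template), as.numeric(search))
}

#' Sub-sample peak offset from a three-point cosine fit
#'
#' Fits `r(k) = R cos(omega * (k - delta))` through the correlations at the
#' integer peak and its two neighbours and returns the fractional peak
#' location `delta` in samples: `omega = acos((r_minus + r_plus) /
#' (2 r_peak))`, `theta = atan2(r_minus - r_plus, 2 r_peak sin(omega))`,
#' `delta = -theta / omega`. Exact on samples of a pure cosine.
#'
#' @param r_minus,r_peak,r_plus Correlations at lags `k-1`, `k`, `k+1`, with
#'   `r_peak` the integer maximum.
#' @return Fractional offset in samples, in `(-0.5, 0.5)` for a genuine
#'   interior peak.
#' @export
#' @examples
#' w <- 0.8
#' cosine_subsample(cos(w * (-1 - 0.3)), cos(w * -0.3), cos(w * (1 - 0.3)))
cosine_subsample <- function(r_minus, r_peak, r_plus) {
  ratio <- (r_minus + r_plus) / (2 * r_peak)
  if (!is.finite(ratio) || abs(ratio) >= 1) {
    stop(structure(class = c("degenerate_fit", "error", "condition"),
                   list(message = "degenerate cosine fit: |(r- + r+)/(2 r0)| >= 1",
                        call = sys.call())))
  }
  omega <- acos(ratio)
  theta <- atan2(r_minus - r_plus, 2 * r_peak * sin(omega))
  -theta / omega
}

# integer peak + cosine refinement over a lag range; earliest lag wins ties.
# Returns shift (samples, relative to lag index 1 of `r`), r at peak, and a
# boundary flag when the peak sits on the range edge.
.refine_peak <- function(r) {
  ipk <- which.max(r)
  boundary <- ipk == 1L || ipk == length(r)
  offset <- 0
  if (!boundary) {
    offset <- tryCatch(
      cosine_subsample(r[ipk - 1L], r[ipk], r[ipk + 1L]),
      degenerate_fit = function(e) 0)          # fall back to the integer peak
  }
  list(peak_index = ipk, offset = offset, r = r[ipk], boundary = boundary)
}

.get_window <- function(x, from, len) {
  from <- max(1L, from)
  to <- min(length(x), from + len - 1L)
  x[from:to]
}

#' Inter-sensor wave travel time for one tap
#'
#' Template: proximal channel `i` over the template window, anchored at tap
#' onset or, when `template_anchor` is given (an arrival-time estimate for
#' channel `i`, e.g. from the previous filter iteration), centred there so
#' the wave stays in-window for distal sensors at slow speeds. Search:
#' distal channel `j` over lags spanning the admissible travel times
#' `spacing/max_speed .. spacing/min_speed` relative to the template start;
#' the integer peak is refined to sub-sample precision by the cosine fit.
#'
#' @param rec A `tap_recording`.
#' @param i,j Channel indices with `i` proximal to `j` (`i < j`).
#' @param array The assumed [sensor_array()] geometry (used for the search
#'   bounds; may differ from the true geometry).
#' @param window A [window_spec()].
#' @param min_speed,max_speed Admissible wave-speed range, m/s.
#' @param template_anchor Optional arrival-time estimate for channel `i`,
#'   seconds after tap onset; `NULL` anchors the template at tap onset.
#' @return A `delay_measurement`: list with `shift` (seconds), `r`, `kind =
#'   "travel-time"`, `i`, `j`, `boundary`.
#' @export
estimate_travel_time <- function(rec, i, j, array, window = window_spec(),
                                 min_speed = 10, max_speed = 150,
                                 template_anchor = NULL) {
  stopifnot(inherits(rec, "tap_recording"), inherits(array, "sensor_array"))
  if (i == j) stop("i and j must be distinct channels", call. = FALSE)
  if (i > j) stop("i must be proximal to j (i < j)", call. = FALSE)
  fs <- rec$sample_rate
  nrec <- nrow(rec$samples)
  spacing <- array$positions[j] - array$positions[i]
  m <- round(window$template_length * fs)
  lag_min <- max(1L, floor(spacing / max_speed * fs))
  lag_max <- ceiling(spacing / min_speed * fs)
  t_start <- if (is.null(template_anchor)) {
    rec$tap_onset
  } else {
    rec$tap_onset + round(template_anchor * fs) - m %/% 2L
  }
  # the full search range must fit the record; pull the template back if not
  t_start <- max(1L, min(t_start, nrec - m + 1L, nrec - (lag_max + m) + 1L))
  if (t_start + m - 1L > nrec) {
    stop("record too short for the template window", call. = FALSE)
  }
  template <- rec$samples[t_start:(t_start + m - 1L), i]
  search <- .get_window(rec$samples[, j], t_start + lag_min,
                        lag_max - lag_min + m)
  r <- normalized_xcorr(template, search)
  pk <- .refine_peak(r)
  shift <- (lag_min + pk$peak_index - 1L + pk$offset) / fs
  structure(list(shift = shift, r = pk$r, kind = "travel-time",
                 i = i, j = j, boundary = pk$boundary),
            class = "delay_measurement")
}

#' Tap-to-tap change in wave arrival at one accelerometer
#'
#' Template: channel `i` of the previous tap, a window of
#' `template_length` centred at `prev_arrival` when supplied (the previous
#' filter iteration's arrival estimate), otherwise anchored at tap onset.
#' Search: the same channel of the current tap over the same anchor widened
#' by `delta_search` on both sides. The returned shift may be negative (wave
#' arriving earlier).
#'
#' @param prev,curr `tap_recording`s for taps `k-1` and `k` (same channel
#'   layout and sample rate).
#' @param i Channel index.
#' @param window A [window_spec()].
#' @param prev_arrival Previous arrival-time estimate for channel `i`,
#'   seconds after tap onset, or `NULL`.
#' @return A `delay_measurement` with `kind = "arrival-change"`.
#' @export
estimate_arrival_delta <- function(prev, curr, i, window = window_spec(),
                                   prev_arrival = NULL) {
  stopifnot(inherits(prev, "tap_recording"), inherits(curr, "tap_recording"))
  if (prev$sample_rate != curr$sample_rate) {
    stop("recordings must share one sample rate", call. = FALSE)
  }
  fs <- prev$sample_rate
  m <- round(window$template_length * fs)
  b <- round(window$delta_search * fs)
  if (is.null(prev_arrival)) {
    t_start <- prev$tap_onset
  } else {
    t_start <- prev$tap_onset + round(prev_arrival * fs) - m %/% 2L
  }
  # clamp the template inside the record, keeping its length
  t_start <- max(1L, min(t_start, nrow(prev$samples) - m + 1L))
  template <- prev$samples[t_start:(t_start + m - 1L), i]
  s_start <- t_start - b
  lead_clip <- max(0L, 1L - s_start)            # samples lost at the left edge
  s_start <- s_start + lead_clip
  search <- .get_window(curr$samples[, i], s_start, m + 2L * b - lead_clip)
  r <- normalized_xcorr(template, search)
  pk <- .refine_peak(r)
  shift <- (pk$peak_index - 1L - b + lead_clip + pk$offset) / fs
  structure(list(shift = shift, r = pk$r, kind = "arrival-change",
                 i = i, j = NA_integer_, boundary = pk$boundary),
            class = "delay_measurement")
}

#' @export
print.delay_measurement <- function(x, ...) {
  cat(sprintf("<delay_measurement> %s ch %s%s: %.3f us (r = %.4f)%s\n",
              x$kind, x$i, if (!is.na(x$j)) paste0("->", x$j) else "",
              x$shift * 1e6, x$r, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Tidy data frame of delay measurements
#'
#' @param measurements A list of `delay_measurement` objects.
#' @param tap_index Optional integer vector of tap indices (recycled).
#' @return A data frame with columns `tap_index`, `kind`, `i`, `j`,
#'   `shift_s`, `r`, `boundary_flag`.
#' @export
delay_measurements_df <- function(measurements, tap_index = NA_integer_) {
  stopifnot(length(measurements) > 0)
  data.frame(
    tap_index = rep_len(tap_index, length(measurements)),
    kind = vapply(measurements, `[[`, "", "kind"),
    i = vapply(measurements, function(m) as.integer(m$i), 0L),
    j = vapply(measurements, function(m) as.integer(m$j), 0L),
    shift_s = vapply(measurements, `[[`, 0, "shift"),
    r = vapply(measurements, `[[`, 0, "r"),
    boundary_flag = vapply(measurements, `[[`, TRUE, "boundary"))
}
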