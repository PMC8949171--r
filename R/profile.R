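# Prescribed wave-speed trajectories over a gait cycle. The walking and
# running templates are parametric stand-ins for literature Achilles-tendon
# loading curves: a raised-cosine stance bump peaking near push-off, a small
# late-swing rise, and a low swing baseline. The amplitude envelope tracks
# the speed profile (signal strength collapses in swing), floored so taps
# never vanish entirely.

.raised_cosine <- function(f, center, halfwidth) {
  d <- abs(f - center)
  ifelse(d <= halfwidth, 0.5 * (1 + cos(pi * d / halfwidth)), 0)
}

#' Prescribed gait-cycle wave-speed profile
#'
#' Builds a deterministic wave-speed profile `c(f)` over gait fraction
#' `f` in `[0, 1)`, plus a matching amplitude envelope. Kinds:
#' \describe{
#'   \item{`constant`}{`c(f) = peak_speed` everywhere, envelope 1.}
#'   \item{`walking`}{baseline 15 m/s in swing, a raised-cosine stance bump
#'     reaching `peak_speed` (default 55 m/s) at 48% of the cycle, plus a
#'     small late-swing rise.}
#'   \item{`running`}{baseline 20 m/s, peak (default 95 m/s) at 40% cycle.}
#' }
#' The amplitude envelope is `max(floor, c(f)/peak_speed)` (default floor
#' 0.1), emulating the collapse of accelerometer signal amplitude during
#' swing; for `constant` it is identically 1.
#'
#' @param kind One of `"walking"`, `"running"`, `"constant"`.
#' @param peak_speed Peak wave speed, m/s; must lie in `(0, max_speed)`.
#' @param baseline Swing-phase baseline speed, m/s.
#' @param peak_at Gait fraction of the stance peak.
#' @param halfwidth Half-width of the stance bump, gait fraction.
#' @param envelope_floor Lower bound on the amplitude envelope.
#' @param max_speed Configured physical ceiling, m/s.
#' @return An object of class `gait_profile` with elements `speed` and
#'   `envelope` (vectorized functions of gait fraction), `kind`,
#'   `peak_speed`.
#' @export
#' @examples
#' p <- make_gait_profile("walking")
#' p$speed(c(0, 0.48, 0.85))
make_gait_profile <- function(kind = c("walking", "running", "constant"),
                              peak_speed = NULL, baseline = NULL,
                              peak_at = NULL, halfwidth = NULL,
                              envelope_floor = 0.1, max_speed = 150) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    walking  = list(peak_speed = 55, baseline = 15, peak_at = 0.48,
                    halfwidth = 0.30),
    running  = list(peak_speed = 95, baseline = 20, peak_at = 0.40,
                    halfwidth = 0.28),
    constant = list(peak_speed = 50, baseline = NA, peak_at = NA,
                    halfwidth = NA))
  peak_speed <- if (is.null(peak_speed)) defaults$peak_speed else peak_speed
  baseline <- if (is.null(baseline)) defaults$baseline else baseline
  peak_at <- if (is.null(peak_at)) defaults$peak_at else peak_at
  halfwidth <- if (is.null(halfwidth)) defaults$halfwidth else halfwidth
  if (!(peak_speed > 0 && peak_speed < max_speed)) {
    stop(sprintf("peak_speed must lie in (0, %g) m/s", max_speed),
         call. = FALSE)
  }

  if (kind == "constant") {
    speed_fn <- function(f) rep(peak_speed, length(f))
    env_fn <- function(f) rep(1, length(f))
  } else {
    force(baseline); force(peak_at); force(halfwidth)
    # small late-swing rise as the tendon re-tensions before heel strike
    swing_rise <- 0.15 * (peak_speed - baseline)
    speed_fn <- function(f) {
      f <- f %% 1
      pmin(baseline +
             (peak_speed - baseline) * .raised_cosine(f, peak_at, halfwidth) +
             swing_rise * .raised_cosine(f, 0.92, 0.12),
           max_speed)
    }
    env_fn <- function(f) pmax(envelope_floor, speed_fn(f) / peak_speed)
  }

  structure(list(kind = kind, speed = speed_fn, envelope = env_fn,
                 peak_speed = peak_speed, max_speed = max_speed),
            class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("<gait_profile> kind '%s', peak %g m/s\n", x$kind, x$peak_speed))
  invisible(x)
}
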