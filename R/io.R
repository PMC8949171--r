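# Plain-text interchange: recordings as CSV with a commented YAML metadata
# header, run configurations as YAML. All times in seconds, positions in
# meters internally; configs accept millimetres via *_mm keys.

#' Write a recording to CSV
#'
#' Long format: one row per sample with columns `tap_index`, `time_s`,
#' `ch1..chn`, preceded by a commented YAML header carrying `sample_rate`,
#' `tap_rate`, `positions` (meters) and, when present, the per-tap true
#' speeds.
#'
#' @param x A `stride_simulation` or list of `tap_recording`s.
#' @param path Output file path.
#' @param tap_rate Tapper rate, Hz (taken from `x` when it is a
#'   `stride_simulation`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, tap_rate = 100) {
  if (inherits(x, "stride_simulation")) {
    tap_rate <- x$tap_rate
    taps <- x$taps
  } else {
    taps <- x
  }
  stopifnot(length(taps) >= 1, inherits(taps[[1]], "tap_recording"))
  fs <- taps[[1]]$sample_rate
  nch <- ncol(taps[[1]]$samples)
  pos <- taps[[1]]$truth$positions
  speeds <- vapply(taps, function(tp)
    if (is.null(tp$truth)) NA_real_ else tp$truth$speed, 0)
  meta <- list(sample_rate = fs, tap_rate = tap_rate, n_channels = nch,
               tap_onset = taps[[1]]$tap_onset)
  if (!is.null(pos)) meta$positions <- pos
  if (!anyNA(speeds)) meta$truth_speeds <- speeds
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
  writeLines(paste("#", hdr), con)
  tabs <- lapply(seq_along(taps), function(k) {
    s <- taps[[k]]$samples
    cbind(tap_index = k, time_s = (seq_len(nrow(s)) - 1) / fs, s)
  })
  tab <- do.call(rbind, tabs)
  colnames(tab) <- c("tap_index", "time_s", paste0("ch", seq_len(nch)))
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV file path.
#' @return A list with `taps` (list of `tap_recording`), `tap_rate`,
#'   `sample_rate`, `positions` (or `NULL`). Schema violations are reported
#'   with the offending field or column name.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0) stop("missing metadata header", call. = FALSE)
  meta <- yaml::yaml.load(paste(sub("^# ?", "", lines[hdr]), collapse = "\n"))
  for (field in c("sample_rate", "tap_rate", "n_channels")) {
    if (is.null(meta[[field]])) {
      stop("metadata missing required field: ", field, call. = FALSE)
    }
  }
  tab <- utils::read.csv(textConnection(lines[-hdr]))
  chcols <- paste0("ch", seq_len(meta$n_channels))
  missing_cols <- setdiff(c("tap_index", "time_s", chcols), names(tab))
  if (length(missing_cols) > 0) {
    stop("recording is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos <- if (is.null(meta$positions)) NULL else as.numeric(meta$positions)
  speeds <- meta$truth_speeds
  taps <- lapply(unique(tab$tap_index), function(k) {
    s <- as.matrix(tab[tab$tap_index == k, chcols, drop = FALSE])
    dimnames(s) <- NULL
    truth <- NULL
    if (!is.null(speeds) && !is.null(pos)) {
      truth <- list(speed = speeds[[k]], arrivals = pos / speeds[[k]],
                    positions = pos)
    } else if (!is.null(pos)) {
      truth <- list(speed = NA_real_, arrivals = NULL, positions = pos)
    }
    structure(list(samples = s, sample_rate = meta$sample_rate,
                   tap_onset = if (is.null(meta$tap_onset)) 1L
                               else as.integer(meta$tap_onset),
                   truth = truth),
              class = "tap_recording")
  })
  list(taps = taps, tap_rate = meta$tap_rate, sample_rate = meta$sample_rate,
       positions = pos)
}

#' Default run configuration
#'
#' Every simulator and estimator parameter with its nominal default:
#' tap amplitude 20 m/s^2, 50 kHz sampling, sensors at 15/25/35/45 mm,
#' damping ratio 0.5 (SD 0.05), natural frequency 1600 Hz (SD 100 Hz),
#' 100 Hz tapping, 100-5000 Hz noise band.
#'
#' @return Nested list with sections `simulate`, `delay`, `kalman`.
#' @export
default_run_config <- function() {
  list(
    simulate = list(
      sample_rate = 50000, tap_rate = 100, stride_duration = 1.1,
      record_duration_ms = 6, amplitude = 20,
      natural_frequency = 1600, frequency_sd = 100,
      damping_ratio = 0.5, damping_sd = 0.05,
      positions_mm = c(15, 25, 35, 45), snr = Inf,
      band = c(100, 5000),
      profile = list(kind = "walking", peak_speed = 55)),
    delay = list(template_length_ms = 2, delta_search_ms = 0.5,
                 min_speed = 10, max_speed = 150),
    kalman = list(constraints = "consecutive", position_sd_mm = 0.5))
}

.validate_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0) {
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) stop("config section ", path, k,
                                   " must be a mapping", call. = FALSE)
      .validate_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

# deep merge of user config over defaults
.merge_config <- function(base, over) {
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]) &&
                     !is.null(names(base[[k]])))
      .merge_config(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

#' Read and validate a run configuration
#'
#' Loads YAML, rejects unknown keys, and fills unset keys from
#' [default_run_config()]. `"inf"`/`".inf"` SNR values map to `Inf`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .validate_keys(cfg, defaults)
  cfg <- .merge_config(defaults, cfg)
  if (is.character(cfg$simulate$snr)) {
    cfg$simulate$snr <- if (tolower(cfg$simulate$snr) %in% c("inf", ".inf"))
      Inf else as.numeric(cfg$simulate$snr)
  }
  cfg
}

# build the package objects a config describes
.config_objects <- function(cfg) {
  sim <- cfg$simulate
  list(
    params = tap_waveform_params(sim$natural_frequency, sim$damping_ratio,
                                 sim$amplitude, sim$frequency_sd,
                                 sim$damping_sd),
    array = sensor_array(sim$positions_mm / 1000),
    noise = noise_spec(sim$snr, sim$band),
    profile = make_gait_profile(sim$profile$kind,
                                peak_speed = sim$profile$peak_speed),
    window = window_spec(cfg$delay$template_length_ms * 1e-3,
                         cfg$delay$delta_search_ms * 1e-3),
    min_speed = cfg$delay$min_speed, max_speed = cfg$delay$max_speed,
    constraints = if (identical(cfg$kalman$constraints, "none")) NULL
                  else cfg$kalman$constraints,
    position_sd = cfg$kalman$position_sd_mm / 1000)
}
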