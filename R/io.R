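# io_formats: readers/writers for every tabular format the toolkit touches,
# plus run configuration. Dialect: CSV with header, comma separator, '.'
# decimal mark, column-name based (never positional). Units are fixed at the
# boundary: newton, newton-metre, centimetre, second. Readers convert nothing.

.device_channels <- list(
  corner_board = c("tl", "tr", "bl", "br"),
  wrench_plate = c("fx", "fy", "fz", "mx", "my", "mz")
)

#' Raw force-plate recording
#'
#' Container for a timestamped multichannel recording from either device:
#' the corner-sensor balance board (four vertical forces `tl`, `tr`, `bl`,
#' `br`, in N) or the six-component reference plate (forces `fx`, `fy`, `fz`
#' in N and moments `mx`, `my`, `mz` in N·m about the plate origin;
#' right-handed frame, z up, x to the subject's right, y anterior).
#'
#' @param device `"corner_board"` or `"wrench_plate"`.
#' @param timestamps Numeric vector of times in seconds, strictly increasing.
#'   The first timestamp need not be 0.
#' @param channels Named list of numeric series, one per expected channel,
#'   all the same length as `timestamps`.
#' @param nominal_rate Nominal sampling rate in Hz (the series are treated as
#'   uniformly sampled at this rate; timestamp jitter is diagnosed, never
#'   corrected).
#'
#' @return An object of class `raw_recording`.
#' @seealso [read_recording()], [write_recording()], [sampling_jitter()]
#' @export
raw_recording <- function(device, timestamps, channels, nominal_rate) {
  device <- match.arg(device, names(.device_channels))
  expected <- .device_channels[[device]]
  missing_ch <- setdiff(expected, names(channels))
  if (length(missing_ch) > 0L) {
    stop_coptools(sprintf("missing channel(s): %s", paste(missing_ch, collapse = ", ")),
                  "format_error")
  }
  channels <- channels[expected]
  n <- length(timestamps)
  lens <- vapply(channels, length, integer(1))
  if (any(lens != n)) {
    stop_coptools("all channel series must share the timestamp length", "format_error")
  }
  if (n >= 2L) {
    bad <- which(diff(timestamps) <= 0)
    if (length(bad) > 0L) {
      stop_coptools(sprintf("timestamps not strictly increasing (first offence at index %d)",
                            bad[1] + 1L), "data_error")
    }
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0) {
    stop_coptools("nominal_rate must be a single positive number", "parameter_error")
  }
  structure(list(device = device, timestamps = as.numeric(timestamps),
                 channels = lapply(channels, as.numeric),
                 nominal_rate = as.numeric(nominal_rate)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf("<raw_recording> %s: %d samples @ %g Hz nominal, %.2f s, channels: %s\n",
              x$device, n, x$nominal_rate,
              if (n > 1) diff(range(x$timestamps)) else 0,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a recording or trajectory
#' @param x A `raw_recording` or `cop_trajectory`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.raw_recording <- function(x) length(x$timestamps)

#' @export
n_samples.cop_trajectory <- function(x) length(x$ml)

#' Read a raw device recording from CSV
#'
#' Parses a comma-separated file with a header row. Required columns:
#' `t, tl, tr, bl, br` for the corner board; `t, fx, fy, fz, mx, my, mz` for
#' the wrench plate. Parsing is column-name based, so column order is free.
#' Rows containing NaN or infinite values are dropped with a message giving
#' the count; rows are never reordered or resampled.
#'
#' @param path Path to an existing CSV file.
#' @param device `"corner_board"` or `"wrench_plate"`.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, device, nominal_rate) {
  device <- match.arg(device, names(.device_channels))
  if (!file.exists(path)) {
    stop_coptools(sprintf("file not found: %s", path), "format_error")
  }
  df <- read.csv(path, check.names = TRUE)
  expected <- c("t", .device_channels[[device]])
  missing_ch <- setdiff(expected, names(df))
  if (length(missing_ch) > 0L) {
    stop_coptools(sprintf("%s: missing column(s): %s", path,
                          paste(missing_ch, collapse = ", ")), "format_error")
  }
  df <- df[expected]
  fin <- vapply(df, is.finite, logical(nrow(df)))
  if (is.null(dim(fin))) fin <- matrix(fin, nrow = nrow(df))
  keep <- rowSums(!fin) == 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_recording: dropped %d row(s) with non-finite values", n_dropped))
    df <- df[keep, , drop = FALSE]
  }
  rec <- raw_recording(device, df$t, as.list(df[.device_channels[[device]]]), nominal_rate)
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Write a raw device recording to CSV
#'
#' Inverse of [read_recording()]: full float precision, comma separator,
#' header row `t` plus the device channels.
#'
#' @param path Output path.
#' @param rec A [raw_recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(path, rec) {
  stopifnot(inherits(rec, "raw_recording"))
  df <- data.frame(t = rec$timestamps, rec$channels, check.names = FALSE)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center-of-pressure trajectory
#'
#' Uniformly sampled medio-lateral (ML, positive to the subject's right) and
#' antero-posterior (AP, positive anterior) COP positions in centimetres,
#' origin at the plate centre.
#'
#' @param ml,ap Numeric series in cm, equal length, all finite.
#' @param rate Sampling rate in Hz.
#' @return An object of class `cop_trajectory`.
#' @export
cop_trajectory <- function(ml, ap, rate) {
  if (length(ml) != length(ap)) {
    stop_coptools("ml and ap series must have equal length", "format_error")
  }
  if (length(ml) > 0L && (!all(is.finite(ml)) || !all(is.finite(ap)))) {
    stop_coptools("COP trajectory contains non-finite values", "data_error")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_coptools("rate must be a single positive number", "parameter_error")
  }
  structure(list(ml = as.numeric(ml), ap = as.numeric(ap), rate = as.numeric(rate)),
            class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory> %d samples @ %g Hz (%.2f s); ML sd %.3f cm, AP sd %.3f cm\n",
              length(x$ml), x$rate, if (length(x$ml) > 1) (length(x$ml) - 1) / x$rate else 0,
              if (length(x$ml) > 1) sd(x$ml) else NA_real_,
              if (length(x$ap) > 1) sd(x$ap) else NA_real_))
  invisible(x)
}

#' Write a COP trajectory to CSV
#'
#' Three columns `t_s, cop_ml_cm, cop_ap_cm` at full float precision; time
#' starts at 0 on the trajectory's uniform grid. Refuses to write NaN values.
#' An empty trajectory yields a header-only file.
#'
#' @param path Output path.
#' @param traj A [cop_trajectory()].
#' @return `path`, invisibly.
#' @export
write_cop <- function(path, traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (length(traj$ml) > 0L && (!all(is.finite(traj$ml)) || !all(is.finite(traj$ap)))) {
    stop_coptools("refusing to write trajectory with non-finite values", "data_error")
  }
  n <- length(traj$ml)
  t_s <- if (n > 0L) (seq_len(n) - 1L) / traj$rate else numeric(0)
  df <- data.frame(t_s = t_s, cop_ml_cm = traj$ml, cop_ap_cm = traj$ap)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a COP trajectory from CSV
#'
#' @param path Path to a file written by [write_cop()] (columns `t_s`,
#'   `cop_ml_cm`, `cop_ap_cm`).
#' @param rate Sampling rate in Hz. If `NULL`, inferred from the median
#'   timestamp interval.
#' @return A [cop_trajectory()].
#' @export
read_cop <- function(path, rate = NULL) {
  if (!file.exists(path)) stop_coptools(sprintf("file not found: %s", path), "format_error")
  df <- read.csv(path)
  need <- c("t_s", "cop_ml_cm", "cop_ap_cm")
  missing_ch <- setdiff(need, names(df))
  if (length(missing_ch) > 0L) {
    stop_coptools(sprintf("%s: missing column(s): %s", path,
                          paste(missing_ch, collapse = ", ")), "format_error")
  }
  if (is.null(rate)) {
    if (nrow(df) < 2L) stop_coptools("cannot infer rate from < 2 samples", "data_error")
    rate <- 1 / median(diff(df$t_s))
  }
  cop_trajectory(df$cop_ml_cm, df$cop_ap_cm, rate)
}

#' Run configuration
#'
#' All tunable constants of the processing pipeline in one validated object.
#' Defaults are the protocol values: 10 Hz low-pass cutoff, design order 4
#' applied forward and backward (zero phase), common 20 Hz rate for alignment
#' and ellipse-area computation, 20 s bipedal / 15 s unipedal analysis
#' segments, 43.3 x 23.8 cm board sensor spans.
#'
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param filter_order Butterworth design order (even).
#' @param common_rate_hz Common rate for device alignment and PEA (Hz).
#' @param bipedal_segment_s,unipedal_segment_s Segment durations (s).
#' @param board_sensor_span_ml,board_sensor_span_ap Distances between sensor
#'   pairs of the board, ML and AP (cm).
#' @param plate_top_offset_cm Vertical distance from the reference-plate
#'   origin to the board's top surface (cm); the moment arm of horizontal
#'   forces.
#' @param board_mass_kg Mass of the board resting on the reference plate (kg).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param force_floor_n Minimum plausible total vertical force (N); frames
#'   below it are treated as an unloaded plate.
#' @param max_lag_s Largest admissible inter-device lag (s).
#' @param random_seed Optional integer seed recorded in run manifests.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(cutoff_hz = 10, filter_order = 4, common_rate_hz = 20,
                       bipedal_segment_s = 20, unipedal_segment_s = 15,
                       board_sensor_span_ml = 43.3, board_sensor_span_ap = 23.8,
                       plate_top_offset_cm = 5.3, board_mass_kg = 3.9,
                       gravity = 9.81, force_floor_n = 50, max_lag_s = 5,
                       random_seed = NULL) {
  cfg <- list(cutoff_hz = cutoff_hz, filter_order = filter_order,
              common_rate_hz = common_rate_hz,
              bipedal_segment_s = bipedal_segment_s,
              unipedal_segment_s = unipedal_segment_s,
              board_sensor_span_ml = board_sensor_span_ml,
              board_sensor_span_ap = board_sensor_span_ap,
              plate_top_offset_cm = plate_top_offset_cm,
              board_mass_kg = board_mass_kg, gravity = gravity,
              force_floor_n = force_floor_n, max_lag_s = max_lag_s,
              random_seed = random_seed)
  pos <- c("cutoff_hz", "common_rate_hz", "bipedal_segment_s", "unipedal_segment_s",
           "board_sensor_span_ml", "board_sensor_span_ap", "board_mass_kg",
           "gravity", "force_floor_n", "max_lag_s")
  for (key in pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_coptools(sprintf("config key '%s' must be a positive number", key),
                    "config_error")
    }
  }
  if (cfg$plate_top_offset_cm < 0) {
    stop_coptools("plate_top_offset_cm must be >= 0", "config_error")
  }
  if (cfg$filter_order %% 2 != 0 || cfg$filter_order < 2) {
    stop_coptools("filter_order must be a positive even integer", "config_error")
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (key in names(x)) cat(sprintf("  %s: %s\n", key, format(x[[key]] %||% "NULL")))
  invisible(x)
}

#' Load a run configuration from a YAML key-value file
#'
#' Missing keys take their [run_config()] defaults; unknown keys are an
#' error (they are usually typos). An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML file of scalar key-value pairs.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_coptools(sprintf("file not found: %s", path), "config_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_coptools(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                  "config_error")
  }
  do.call(run_config, raw)
}

#' Write JSON reports
#'
#' Thin wrapper fixing the dialect used for all metric/report outputs:
#' auto-unboxed scalars, full precision, pretty-printed.
#'
#' @param x A list (report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
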