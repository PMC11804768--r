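# calibration: per-sensor linear calibration of the corner board from a
# zero-load recording and a known-mass recording (the protocol records 200
# samples empty, then 200 samples with 55 kg centred on the board; the 5 Hz
# calibration rate is metadata only). A centred mass loads each corner
# equally, so the expected per-sensor force is mass*g/4.

#' Fit a per-sensor linear calibration
#'
#' For each corner channel c: `offset_c = mean(zero)` and
#' `gain_c = (known_mass_kg * g / 4) / (mean(load) - offset_c)` (N per raw
#' unit). Sample means over the full windows are used.
#'
#' @param zero_rec Corner-board [raw_recording()] taken with no load.
#' @param load_rec Corner-board [raw_recording()] taken with `known_mass_kg`
#'   centred on the board.
#' @param known_mass_kg Calibration mass in kg (> 0); protocol value 55.
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `calibration_model` with per-channel `offset`
#'   and `gain` vectors.
#' @export
fit_linear_calibration <- function(zero_rec, load_rec, known_mass_kg, g = 9.81) {
  for (rec in list(zero_rec, load_rec)) {
    if (!inherits(rec, "raw_recording") || rec$device != "corner_board") {
      stop_coptools("calibration requires corner_board recordings", "calibration_error")
    }
  }
  if (!is.numeric(known_mass_kg) || known_mass_kg <= 0) {
    stop_coptools("known_mass_kg must be > 0", "calibration_error")
  }
  chs <- .device_channels$corner_board
  offset <- vapply(chs, function(ch) mean(zero_rec$channels[[ch]]), numeric(1))
  loaded <- vapply(chs, function(ch) mean(load_rec$channels[[ch]]), numeric(1))
  delta <- loaded - offset
  if (any(delta <= 0)) {
    bad <- chs[delta <= 0][1]
    stop_coptools(sprintf("channel '%s' shows no load increase over zero recording", bad),
                  "calibration_error")
  }
  expected <- known_mass_kg * g / 4
  gain <- expected / delta
  structure(list(offset = offset, gain = gain, known_mass_kg = known_mass_kg, g = g),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> mass %g kg, g %g m/s^2\n", x$known_mass_kg, x$g))
  print(data.frame(offset = x$offset, gain_n_per_unit = x$gain))
  invisible(x)
}

#' Apply a linear calibration to a corner-board recording
#'
#' Maps each channel `x -> gain * (x - offset)`; timestamps are unchanged.
#'
#' @param rec Corner-board [raw_recording()].
#' @param cal A [fit_linear_calibration()] model.
#' @return Calibrated [raw_recording()] (forces in N).
#' @export
apply_calibration <- function(rec, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (!inherits(rec, "raw_recording") || rec$device != "corner_board") {
    stop_coptools("apply_calibration expects a corner_board recording", "calibration_error")
  }
  chs <- .device_channels$corner_board
  out <- rec
  for (ch in chs) {
    out$channels[[ch]] <- cal$gain[[ch]] * (rec$channels[[ch]] - cal$offset[[ch]])
  }
  out
}

#' Serialize / load a calibration model (JSON)
#'
#' @param cal A `calibration_model`.
#' @param path File path.
#' @return `write_calibration`: `path` invisibly; `read_calibration`: the model.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  write_report_json(list(offset = as.list(cal$offset), gain = as.list(cal$gain),
                         known_mass_kg = cal$known_mass_kg, g = cal$g), path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_coptools(sprintf("file not found: %s", path), "format_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(offset = unlist(x$offset), gain = unlist(x$gain),
                 known_mass_kg = x$known_mass_kg, g = x$g),
            class = "calibration_model")
}
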