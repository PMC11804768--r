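# cop_compute: COP trajectories from corner forces (index device) and from
# the six-component wrench with stacked-plate corrections (reference device).
# Shared axis frame: ml = x, positive to the subject's right; ap = y,
# positive anterior; origin at the plate centre; output in cm.

#' COP from four corner-sensor forces
#'
#' Per sample, with total force `F = tl + tr + bl + br`:
#' `ml = (span_ml / 2) * ((tr + br) - (tl + bl)) / F` and
#' `ap = (span_ap / 2) * ((tl + tr) - (bl + br)) / F`.
#' The result is invariant to uniform scaling of all four forces.
#'
#' @param rec Calibrated corner-board [raw_recording()] (forces in N).
#' @param span_ml,span_ap Distances between the sensor pairs (cm).
#' @param force_floor_n Minimum admissible total force (N); any sample below
#'   it raises an unloaded-plate error naming the first offending sample.
#' @return A [cop_trajectory()] at the recording's nominal rate.
#' @export
cop_from_corner_forces <- function(rec, span_ml = 43.3, span_ap = 23.8,
                                   force_floor_n = 50) {
  if (!inherits(rec, "raw_recording") || rec$device != "corner_board") {
    stop_coptools("cop_from_corner_forces expects a corner_board recording",
                  "parameter_error")
  }
  ch <- rec$channels
  f_total <- ch$tl + ch$tr + ch$bl + ch$br
  low <- which(f_total < force_floor_n)
  if (length(low) > 0L) {
    stop_coptools(sprintf("total force below %g N floor (first offending sample: %d)",
                          force_floor_n, low[1]), "unloaded_error")
  }
  ml <- (span_ml / 2) * ((ch$tr + ch$br) - (ch$tl + ch$bl)) / f_total
  ap <- (span_ap / 2) * ((ch$tl + ch$tr) - (ch$bl + ch$br)) / f_total
  cop_trajectory(ml, ap, rec$nominal_rate)
}

#' COP from a six-component wrench with stacked-plate corrections
#'
#' The board sits on top of the reference plate, so the plate's vertical
#' force is reduced by the board's weight and the moment arm of horizontal
#' forces is extended to the board surface. With `fz' = fz -
#' added_mass_kg * g` and moment arm `d` (the top offset):
#' `ml = (-my - fx * d) / fz'` and `ap = (mx - fy * d) / fz'`
#' (metres, converted to cm). Right-handed frame, z up, moments about the
#' plate origin.
#'
#' @param rec Wrench-plate [raw_recording()] (N, N m).
#' @param top_offset_cm Vertical distance from the plate origin to the board
#'   surface (cm).
#' @param added_mass_kg Mass resting on the plate besides the subject (kg),
#'   i.e. the board.
#' @param g Gravitational acceleration (m/s^2).
#' @param force_floor_n Minimum admissible corrected vertical force (N).
#' @return A [cop_trajectory()] at the recording's nominal rate.
#' @export
cop_from_wrench <- function(rec, top_offset_cm = 5.3, added_mass_kg = 3.9,
                            g = 9.81, force_floor_n = 50) {
  if (!inherits(rec, "raw_recording") || rec$device != "wrench_plate") {
    stop_coptools("cop_from_wrench expects a wrench_plate recording", "parameter_error")
  }
  ch <- rec$channels
  fzp <- ch$fz - added_mass_kg * g
  low <- which(fzp < force_floor_n)
  if (length(low) > 0L) {
    stop_coptools(sprintf("corrected vertical force below %g N floor (first offending sample: %d); added-mass correction may exceed the load",
                          force_floor_n, low[1]), "unloaded_error")
  }
  d_m <- top_offset_cm / 100
  ml <- 100 * (-ch$my - ch$fx * d_m) / fzp
  ap <- 100 * (ch$mx - ch$fy * d_m) / fzp
  cop_trajectory(ml, ap, rec$nominal_rate)
}

#' COP from either device
#'
#' Dispatch helper: corner-board recordings go through
#' [cop_from_corner_forces()], wrench recordings through
#' [cop_from_wrench()], with geometry taken from the run configuration.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [run_config()].
#' @return A [cop_trajectory()].
#' @export
compute_cop <- function(rec, cfg = run_config()) {
  if (rec$device == "corner_board") {
    cop_from_corner_forces(rec, cfg$board_sensor_span_ml, cfg$board_sensor_span_ap,
                           cfg$force_floor_n)
  } else {
    cop_from_wrench(rec, cfg$plate_top_offset_cm, cfg$board_mass_kg, cfg$gravity,
                    cfg$force_floor_n)
  }
}
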