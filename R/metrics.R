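# sway_metrics: the six COP parameters of one analysis segment.
# SD of ML/AP displacement (cm), mean velocity per axis (cm/s), total
# pathlength (cm) and the 95% prediction ellipse area (cm^2, computed from
# the 20 Hz version of the segment).

#' SD of COP displacement
#'
#' Sample standard deviation (n - 1 denominator) of a displacement series
#' about its segment mean.
#'
#' @param series Numeric series (cm), length >= 2.
#' @return SD in cm.
#' @export
sd_displacement <- function(series) {
  if (length(series) < 2L) stop_coptools("need at least 2 samples", "parameter_error")
  sd(series)
}

#' Mean COP velocity along one axis
#'
#' Sum of absolute sample-to-sample displacements divided by the elapsed
#' time `(n - 1) / rate` (i.e. per-axis pathlength over time).
#'
#' @param series Numeric series (cm), length >= 2.
#' @param rate Sampling rate (Hz).
#' @return Mean velocity in cm/s.
#' @export
mean_velocity <- function(series, rate) {
  if (length(series) < 2L) stop_coptools("need at least 2 samples", "parameter_error")
  sum(abs(diff(series))) / ((length(series) - 1L) / rate)
}

#' Total COP pathlength
#'
#' Sum of Euclidean step lengths `sqrt(dml^2 + dap^2)` over the segment.
#'
#' @param ml,ap Numeric series (cm), equal length >= 2.
#' @return Pathlength in cm.
#' @export
path_length <- function(ml, ap) {
  if (length(ml) != length(ap)) stop_coptools("ml and ap length mismatch", "parameter_error")
  if (length(ml) < 2L) stop_coptools("need at least 2 samples", "parameter_error")
  sum(sqrt(diff(ml)^2 + diff(ap)^2))
}

#' Small-sample 95% prediction-ellipse factor
#'
#' `c(n) = ((n + 1) / n) * (2 (n - 1) / (n - 2)) * F_0.95(2, n - 2)`,
#' the scaling applied to `sqrt(det S)` for a prediction (not confidence)
#' ellipse expected to contain 95% of future COP positions. As n grows it
#' approaches the chi-square limit `qchisq(0.95, 2) = 5.9915`.
#'
#' @param n Number of samples (> 3).
#' @return The factor c(n).
#' @export
prediction_ellipse_factor <- function(n) {
  if (n <= 3) stop_coptools("prediction ellipse needs n > 3", "parameter_error")
  ((n + 1) / n) * (2 * (n - 1) / (n - 2)) * qf(0.95, 2, n - 2)
}

#' 95% prediction ellipse area
#'
#' `PEA = pi * c(n) * sqrt(det S)` with `S` the 2x2 sample covariance of
#' `(ml, ap)` and `c(n)` the small-sample prediction factor
#' ([prediction_ellipse_factor()]). A singular covariance (zero variance on
#' an axis) yields area 0 with a degenerate-ellipse warning.
#'
#' @param ml,ap Numeric series (cm), equal length, n >= 4; by convention the
#'   20 Hz version of the segment.
#' @return Area in cm^2.
#' @export
prediction_ellipse_area_95 <- function(ml, ap) {
  if (length(ml) != length(ap)) stop_coptools("ml and ap length mismatch", "parameter_error")
  n <- length(ml)
  if (n < 4L) stop_coptools("prediction ellipse needs at least 4 samples", "parameter_error")
  S <- stats::cov(cbind(ml, ap))
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (det_s <= 0) {
    warn_coptools("degenerate ellipse: singular COP covariance, area set to 0",
                  "degenerate_warning")
    return(0)
  }
  pi * prediction_ellipse_factor(n) * sqrt(det_s)
}

#' All six sway metrics of a segment
#'
#' SD of displacement, mean velocity and pathlength are computed at the
#' segment's native rate; the 95% prediction ellipse area is computed after
#' decimation to `cfg$common_rate_hz` when the trajectory is sampled faster.
#'
#' @param traj A [cop_trajectory()].
#' @param seg A [select_segment()] descriptor valid for `traj` (or `NULL` to
#'   use the whole trajectory).
#' @param cfg A [run_config()].
#' @return An object of class `sway_metrics` with fields `sd_ml_cm`,
#'   `sd_ap_cm`, `v_ml_cm_s`, `v_ap_cm_s`, `pathlength_cm`, `pea95_cm2`,
#'   `segment_rate_hz`, `segment_duration_s`.
#' @export
compute_sway_metrics <- function(traj, seg = NULL, cfg = run_config()) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (is.null(seg)) {
    ml <- traj$ml; ap <- traj$ap
  } else {
    if (seg$start < 1L || seg$start + seg$length - 1L > length(traj$ml)) {
      stop_coptools("segment does not fit the trajectory", "segment_error")
    }
    idx <- seq.int(seg$start, seg$start + seg$length - 1L)
    ml <- traj$ml[idx]; ap <- traj$ap[idx]
  }
  rate <- traj$rate
  seg_traj <- cop_trajectory(ml, ap, rate)
  pea_traj <- if (rate > cfg$common_rate_hz) {
    decimate_trajectory(seg_traj, cfg$common_rate_hz)
  } else {
    seg_traj
  }
  structure(list(
    sd_ml_cm = sd_displacement(ml),
    sd_ap_cm = sd_displacement(ap),
    v_ml_cm_s = mean_velocity(ml, rate),
    v_ap_cm_s = mean_velocity(ap, rate),
    pathlength_cm = path_length(ml, ap),
    pea95_cm2 = prediction_ellipse_area_95(pea_traj$ml, pea_traj$ap),
    segment_rate_hz = rate,
    segment_duration_s = (length(ml) - 1L) / rate
  ), class = "sway_metrics")
}

#' @export
print.sway_metrics <- function(x, ...) {
  cat(sprintf(paste0("<sway_metrics> %.2f s @ %g Hz\n",
                     "  SD ml/ap: %.3f / %.3f cm\n",
                     "  velocity ml/ap: %.3f / %.3f cm/s\n",
                     "  pathlength: %.3f cm; 95%% PEA: %.3f cm^2\n"),
              x$segment_duration_s, x$segment_rate_hz, x$sd_ml_cm, x$sd_ap_cm,
              x$v_ml_cm_s, x$v_ap_cm_s, x$pathlength_cm, x$pea95_cm2))
  invisible(x)
}

#' @export
as.list.sway_metrics <- function(x, ...) unclass(x)
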