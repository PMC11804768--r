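# signal_pipeline: filtering, downsampling, dual-device alignment, stable
# onset detection, segment selection and sampling-jitter diagnostics.
#
# Processing order mirrors the acquisition protocol: (1) low-pass filter the
# raw sensor channels, (2) downsample copies to the common rate and estimate
# the inter-device lag by cross-correlation, (3) trim both recordings so they
# start synchronously, (4) pick the analysis segment (central 20 s bipedal /
# 15 s unipedal window after stance onset) at each device's native rate.

#' Zero-phase low-pass Butterworth filter
#'
#' Designs an `order`-point Butterworth low-pass filter and applies it
#' forward and backward, giving zero phase lag and the squared single-pass
#' magnitude response (DC gain exactly 1). Edge transients are controlled by
#' odd-symmetric signal extension plus steady-state initial conditions, so a
#' constant series passes through unchanged to machine precision.
#'
#' @param x Numeric series.
#' @param rate Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), must be below the Nyquist rate.
#' @param order Design order (positive even integer); the effective
#'   bidirectional attenuation is twice this order's.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, rate, cutoff = 10, order = 4) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= rate / 2) {
    stop_coptools(sprintf("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)",
                          cutoff, rate / 2), "parameter_error")
  }
  if (order %% 2 != 0 || order < 2) {
    stop_coptools("filter order must be a positive even integer", "parameter_error")
  }
  n <- length(x)
  if (n <= 3 * order) {
    stop_coptools(sprintf("series too short (%d) for order-%d zero-phase filtering",
                          n, order), "parameter_error")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  nb <- length(bf$b)
  na <- length(bf$a)
  padlen <- min(3L * max(na, nb), n - 1L)
  # odd extension around both endpoints (scipy-filtfilt style padding)
  front <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  xp <- c(front, x, back)
  dc_gain <- sum(bf$b) / sum(bf$a)
  one_pass <- function(z) {
    as.numeric(signal::filter(bf, z,
                              init.x = rep(z[1], nb - 1L),
                              init.y = rep(z[1] * dc_gain, na - 1L)))
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[seq(padlen + 1L, padlen + n)]
}

#' Downsample by integer decimation
#'
#' Keeps every `rate_in / rate_out`-th sample starting at the first one.
#' The input is assumed already low-pass filtered below `rate_out / 2`;
#' no interpolation is performed.
#'
#' @param x Numeric series.
#' @param rate_in,rate_out Sampling rates (Hz); `rate_in` must be an integer
#'   multiple of `rate_out`.
#' @return Decimated series of length `ceiling(length(x) / ratio)`.
#' @export
downsample <- function(x, rate_in, rate_out) {
  ratio <- rate_in / rate_out
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop_coptools(sprintf("rate_in (%g) must be an integer multiple of rate_out (%g)",
                          rate_in, rate_out), "parameter_error")
  }
  x[seq.int(1L, length(x), by = as.integer(round(ratio)))]
}

#' Decimate a COP trajectory to a lower rate
#'
#' @param traj A [cop_trajectory()].
#' @param rate_out Target rate (Hz), an integer divisor of the trajectory rate.
#' @return A [cop_trajectory()] at `rate_out`.
#' @export
decimate_trajectory <- function(traj, rate_out) {
  stopifnot(inherits(traj, "cop_trajectory"))
  cop_trajectory(downsample(traj$ml, traj$rate, rate_out),
                 downsample(traj$ap, traj$rate, rate_out), rate_out)
}

#' Estimate the lag between two series by normalized cross-correlation
#'
#' Both series must share one sampling rate. The lag maximizing the Pearson
#' correlation of the mean-removed overlapping parts is returned; a positive
#' lag means `b` started later than `a` (an event at index `i + lag` of `a`
#' appears at index `i` of `b`). Ties are broken toward the smallest
#' absolute lag. If the best correlation is negative the lag of the largest
#' absolute correlation is returned with attribute
#' `negative_correlation = TRUE` and a warning.
#'
#' @param a,b Numeric series (length > 2 * `max_lag`).
#' @param max_lag Largest lag searched, in samples.
#' @return Integer lag in samples (with attributes `correlation` and
#'   `negative_correlation`).
#' @export
estimate_lag <- function(a, b, max_lag) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sd(a) == 0 || sd(b) == 0) {
    stop_coptools("zero-variance input: cannot align", "alignment_error")
  }
  n <- min(length(a), length(b))
  if (n <= 2 * max_lag) {
    stop_coptools("series too short for the requested maximum lag", "alignment_error")
  }
  a <- a - mean(a); b <- b - mean(b)
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(s) {
    if (s >= 0) {
      ai <- seq.int(1L + s, n); bi <- seq.int(1L, n - s)
    } else {
      ai <- seq.int(1L, n + s); bi <- seq.int(1L - s, n)
    }
    suppressWarnings(stats::cor(a[ai], b[bi]))
  }, numeric(1))
  r[is.na(r)] <- 0
  use_abs <- max(r) <= 0
  score <- if (use_abs) abs(r) else r
  best <- max(score)
  cand <- lags[score >= best - 1e-12]
  lag <- cand[which.min(abs(cand))]
  if (use_abs) {
    warn_coptools("series are anticorrelated at the best lag; sign flag set",
                  "alignment_warning")
  }
  structure(as.integer(lag),
            correlation = r[match(lag, lags)],
            negative_correlation = use_abs)
}

.slice_recording <- function(rec, start, len) {
  idx <- seq.int(start, start + len - 1L)
  rec$timestamps <- rec$timestamps[idx]
  rec$channels <- lapply(rec$channels, function(ch) ch[idx])
  rec
}

# Series used to match the two devices: the board's bottom-left sensor, or
# for the wrench device a virtual bottom-left corner force reconstructed
# from its COP and vertical force (the reference plate exposes no corner
# channels in wrench form).
.matching_series <- function(rec, cfg) {
  if (rec$device == "corner_board") {
    return(rec$channels$bl)
  }
  fzp <- rec$channels$fz - cfg$board_mass_kg * cfg$gravity
  fzp[fzp < cfg$force_floor_n] <- cfg$force_floor_n
  d_m <- cfg$plate_top_offset_cm / 100
  u <- (-rec$channels$my - rec$channels$fx * d_m) / fzp * 100 / (cfg$board_sensor_span_ml / 2)
  v <- (rec$channels$mx - rec$channels$fy * d_m) / fzp * 100 / (cfg$board_sensor_span_ap / 2)
  fzp / 4 * (1 - u) * (1 - v)
}

#' Align two device recordings by cross-correlation
#'
#' The matching series of each device (bottom-left sensor force, or its
#' virtual equivalent for the wrench plate) is low-pass filtered and
#' downsampled to `cfg$common_rate_hz`; the lag maximizing their normalized
#' cross-correlation is rescaled to each native rate by rounding, leading
#' samples of the earlier-started recording are trimmed, and both ends are
#' trimmed to a common duration.
#'
#' @param idx Index-device [raw_recording()] (corner board).
#' @param ref Reference-device [raw_recording()] (wrench plate).
#' @param cfg A [run_config()].
#' @param prefiltered If `TRUE` the matching series are taken as already
#'   low-pass filtered and are not filtered again.
#' @return List with elements `index` and `reference` (trimmed recordings),
#'   `lag_common_samples`, and `lag_s`.
#' @export
align_recordings <- function(idx, ref, cfg = run_config(), prefiltered = FALSE) {
  series <- lapply(list(idx = idx, ref = ref), function(rec) {
    s <- .matching_series(rec, cfg)
    if (!prefiltered) {
      s <- lowpass_zero_phase(s, rec$nominal_rate, cfg$cutoff_hz, cfg$filter_order)
    }
    downsample(s, rec$nominal_rate, cfg$common_rate_hz)
  })
  max_lag <- as.integer(round(cfg$max_lag_s * cfg$common_rate_hz))
  lag <- estimate_lag(series$idx, series$ref, max_lag)
  if (abs(lag) >= max_lag) {
    stop_coptools(sprintf("estimated lag (%.2f s) reaches the maximum allowed (%.2f s); recordings may not overlap",
                          lag / cfg$common_rate_hz, cfg$max_lag_s), "alignment_error")
  }
  trim <- function(rec, lag_samples) {
    if (lag_samples > 0) .slice_recording(rec, 1L + lag_samples,
                                          n_samples(rec) - lag_samples) else rec
  }
  lag_idx <- as.integer(round(lag * idx$nominal_rate / cfg$common_rate_hz))
  lag_ref <- as.integer(round(-lag * ref$nominal_rate / cfg$common_rate_hz))
  idx2 <- trim(idx, lag_idx)    # positive lag: reference started later
  ref2 <- trim(ref, lag_ref)
  dur <- min((n_samples(idx2) - 1L) / idx2$nominal_rate,
             (n_samples(ref2) - 1L) / ref2$nominal_rate)
  if (dur <= 0) stop_coptools("no common duration after alignment", "alignment_error")
  keep <- function(rec) .slice_recording(rec, 1L,
                                         as.integer(floor(dur * rec$nominal_rate)) + 1L)
  list(index = keep(idx2), reference = keep(ref2),
       lag_common_samples = as.integer(lag),
       lag_s = as.numeric(lag) / cfg$common_rate_hz)
}

#' Low-pass filter every channel of a recording
#'
#' @param rec A [raw_recording()].
#' @param cfg A [run_config()] supplying `cutoff_hz` and `filter_order`.
#' @return The recording with all channels filtered (timestamps unchanged).
#' @export
filter_recording <- function(rec, cfg = run_config()) {
  rec$channels <- lapply(rec$channels, lowpass_zero_phase,
                         rate = rec$nominal_rate, cutoff = cfg$cutoff_hz,
                         order = cfg$filter_order)
  rec
}

#' Total vertical force of a recording
#'
#' Sum of the four corner channels (board) or the `fz` channel (wrench).
#'
#' @param rec A [raw_recording()].
#' @return Numeric series in N.
#' @export
total_vertical_force <- function(rec) {
  if (rec$device == "corner_board") {
    rec$channels$tl + rec$channels$tr + rec$channels$bl + rec$channels$br
  } else {
    rec$channels$fz
  }
}

#' Detect the first stable-stance sample
#'
#' First index from which the total vertical force stays within +/- 5% of
#' the series median for a continuous 2 s window. If no such window exists,
#' index 1 is returned with a warning (fallback: analyse from the start).
#'
#' @param total_force Numeric series (N).
#' @param rate Sampling rate (Hz).
#' @param tolerance Relative band half-width around the median (default 0.05).
#' @param window_s Required stable duration in seconds (default 2).
#' @return Integer sample index (1-based).
#' @export
detect_stable_onset <- function(total_force, rate, tolerance = 0.05, window_s = 2) {
  win <- max(2L, as.integer(round(window_s * rate)))
  if (length(total_force) <= win) {
    stop_coptools("series shorter than the stability window", "parameter_error")
  }
  med <- median(total_force)
  ok <- abs(total_force - med) <= tolerance * abs(med)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= win)
  if (length(hit) == 0L) {
    warn_coptools("no stable 2 s window found; falling back to recording start",
                  "onset_warning")
    return(1L)
  }
  as.integer(starts[hit[1]])
}

#' Select the analysis segment of a trajectory
#'
#' Central window of the post-onset span: 20 s for bipedal tasks, 15 s for
#' unipedal tasks (durations from the run configuration), at the signal's
#' native rate.
#'
#' @param traj_len Total number of samples available.
#' @param rate Sampling rate (Hz).
#' @param task `"bipedal"` or `"unipedal"`.
#' @param onset First stable sample (1-based), see [detect_stable_onset()].
#' @param cfg A [run_config()].
#' @return An object of class `segment` with `start`, `length` (samples) and
#'   `rate`.
#' @export
select_segment <- function(traj_len, rate, task = c("bipedal", "unipedal"),
                           onset = 1L, cfg = run_config()) {
  task <- match.arg(task)
  dur_s <- if (task == "bipedal") cfg$bipedal_segment_s else cfg$unipedal_segment_s
  seg_len <- as.integer(round(dur_s * rate))
  avail <- traj_len - onset + 1L
  if (avail < seg_len) {
    stop_coptools(sprintf("insufficient duration: %.2f s available after onset, %.2f s required",
                          avail / rate, dur_s), "segment_error")
  }
  start <- onset + as.integer(floor((avail - seg_len) / 2))
  structure(list(start = start, length = seg_len, rate = rate, task = task),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %s: samples %d..%d @ %g Hz (%.2f s)\n", x$task, x$start,
              x$start + x$length - 1L, x$rate, x$length / x$rate))
  invisible(x)
}

#' Sampling-interval jitter diagnostics
#'
#' Per-recording standard deviation of the inter-sample intervals (ms), and
#' the group mean with its t-based 95% confidence interval across
#' recordings. Jitter is reported, never corrected: the series are treated
#' as uniformly sampled at the nominal rate throughout the pipeline.
#'
#' @param recordings List of [raw_recording()] objects or of numeric
#'   timestamp vectors (seconds), each with at least 3 timestamps.
#' @return An object of class `jitter_stats`: `sd_ms` (per recording),
#'   `mean_ms`, `ci95_ms`.
#' @export
sampling_jitter <- function(recordings) {
  ts_list <- lapply(recordings, function(x) {
    if (inherits(x, "raw_recording")) x$timestamps else as.numeric(x)
  })
  if (any(vapply(ts_list, length, integer(1)) < 3L)) {
    stop_coptools("each recording needs at least 3 timestamps", "parameter_error")
  }
  sds <- vapply(ts_list, function(t) sd(diff(t)) * 1000, numeric(1))
  m <- length(sds)
  mean_ms <- mean(sds)
  ci <- if (m >= 2L) {
    half <- qt(0.975, m - 1L) * sd(sds) / sqrt(m)
    c(mean_ms - half, mean_ms + half)
  } else {
    c(mean_ms, mean_ms)
  }
  structure(list(sd_ms = sds, mean_ms = mean_ms, ci95_ms = ci),
            class = "jitter_stats")
}

#' @export
print.jitter_stats <- function(x, ...) {
  cat(sprintf("<jitter_stats> %d recording(s); mean interval SD %.3f ms (95%% CI %.3f..%.3f)\n",
              length(x$sd_ms), x$mean_ms, x$ci95_ms[1], x$ci95_ms[2]))
  invisible(x)
}

#' Full preprocessing of a dual-device trial
#'
#' Filters both recordings, aligns them, detects stance onset on the total
#' vertical force of each device (the later of the two wins), and slices
#' both to the task's analysis segment at their native rates.
#'
#' @param idx Index-device [raw_recording()] (corner board, calibrated).
#' @param ref Reference-device [raw_recording()] (wrench plate).
#' @param task `"bipedal"` or `"unipedal"`.
#' @param cfg A [run_config()].
#' @return List with segment-sliced `index` and `reference` recordings, the
#'   two `segment` descriptors, `lag_s`, and jitter statistics of the input
#'   pair.
#' @export
preprocess_recordings <- function(idx, ref, task = c("bipedal", "unipedal"),
                                  cfg = run_config()) {
  task <- match.arg(task)
  jitter <- sampling_jitter(list(idx, ref))
  idx_f <- filter_recording(idx, cfg)
  ref_f <- filter_recording(ref, cfg)
  al <- align_recordings(idx_f, ref_f, cfg, prefiltered = TRUE)
  onset_s <- max(vapply(al[c("index", "reference")], function(rec) {
    (detect_stable_onset(total_vertical_force(rec), rec$nominal_rate) - 1L) /
      rec$nominal_rate
  }, numeric(1)))
  out <- list(lag_s = al$lag_s, jitter = jitter)
  for (side in c("index", "reference")) {
    rec <- al[[side]]
    onset_i <- as.integer(round(onset_s * rec$nominal_rate)) + 1L
    seg <- select_segment(n_samples(rec), rec$nominal_rate, task, onset_i, cfg)
    out[[side]] <- .slice_recording(rec, seg$start, seg$length)
    out[[paste0("segment_", side)]] <- seg
  }
  out
}
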