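# synthetic_data: seeded quiet-stance sway simulator with dual-device
# rendering. Sway is a per-axis Ornstein-Uhlenbeck (mean-reverting) process,
# the simplest stationary model with power concentrated in the slow 0-1 Hz
# band; the truth trajectory is band-limited so that it is fully resolved by
# both device rates. Device rendering inverts the COP formulas exactly and
# then adds the configured imperfections: inter-device clock lag,
# timestamp jitter, per-channel force noise, and the index device's
# broadband medio-lateral noise above a corner frequency.

#' Sway-simulator configuration
#'
#' Defaults emulate quiet bipedal stance of a healthy adult on the two-device
#' stack: stationary sway SD 0.17 cm ML / 0.42 cm AP with a 1.5 s
#' mean-reversion time constant, 79.4 kg subject, 40 Hz board over a 100 Hz
#' plate started 0.65 s apart, 1 ms timestamp jitter on the board, small
#' white sensor noise on both devices, and a 1.5 N broadband ML noise term
#' on the board above 2.5 Hz (the index device's characteristic error).
#'
#' @param sd_ml_cm,sd_ap_cm Stationary sway SD per axis (cm).
#' @param tau_ml_s,tau_ap_s Mean-reversion time constants (s).
#' @param sway_bandwidth_hz Band limit applied to the truth trajectory (Hz).
#' @param subject_mass_kg Subject mass (kg).
#' @param duration_s Recorded duration per device (s).
#' @param rate_board_hz,rate_plate_hz Device sampling rates (Hz).
#' @param device_lag_s Clock lag: the board starts this much later (s).
#' @param jitter_board_ms,jitter_plate_ms SD of timestamp-interval noise (ms).
#' @param noise_board_n,noise_plate_n White per-channel force noise SD (N).
#' @param ml_noise_board_n SD of the board's extra broadband ML force noise
#'   (N), injected differentially at sensor level.
#' @param ml_noise_corner_hz Corner frequency of that noise term (Hz).
#' @param span_ml_cm,span_ap_cm Board sensor spans (cm).
#' @param top_offset_cm Plate-origin-to-board-surface distance (cm).
#' @param board_mass_kg Board mass (kg).
#' @param gravity m/s^2.
#' @return An object of class `sway_sim_config`.
#' @export
sway_sim_config <- function(sd_ml_cm = 0.17, sd_ap_cm = 0.42,
                            tau_ml_s = 1.5, tau_ap_s = 1.5,
                            sway_bandwidth_hz = 4,
                            subject_mass_kg = 79.4, duration_s = 35,
                            rate_board_hz = 40, rate_plate_hz = 100,
                            device_lag_s = 0.65,
                            jitter_board_ms = 1, jitter_plate_ms = 0,
                            noise_board_n = 0.2, noise_plate_n = 0.05,
                            ml_noise_board_n = 1.5, ml_noise_corner_hz = 2.5,
                            span_ml_cm = 43.3, span_ap_cm = 23.8,
                            top_offset_cm = 5.3, board_mass_kg = 3.9,
                            gravity = 9.81) {
  cfg <- as.list(environment())
  if (cfg$sd_ml_cm < 0 || cfg$sd_ap_cm < 0) {
    stop_coptools("sway SDs must be >= 0", "parameter_error")
  }
  if (cfg$tau_ml_s <= 0 || cfg$tau_ap_s <= 0) {
    stop_coptools("time constants must be > 0", "parameter_error")
  }
  for (key in c("subject_mass_kg", "duration_s", "rate_board_hz", "rate_plate_hz",
                "span_ml_cm", "span_ap_cm", "gravity", "sway_bandwidth_hz")) {
    if (cfg[[key]] <= 0) stop_coptools(sprintf("%s must be > 0", key), "parameter_error")
  }
  if (cfg$device_lag_s < 0) stop_coptools("device_lag_s must be >= 0", "parameter_error")
  if (min(cfg$rate_board_hz, cfg$rate_plate_hz) <= 2 * cfg$sway_bandwidth_hz) {
    stop_coptools("device rates must exceed twice the sway bandwidth", "parameter_error")
  }
  structure(cfg, class = "sway_sim_config")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.master_rate <- function(scfg) {
  a <- as.integer(round(scfg$rate_board_hz))
  b <- as.integer(round(scfg$rate_plate_hz))
  a * b / .gcd(a, b)
}

# exact discretization of a stationary OU process
.ou_series <- function(n, dt, sd, tau) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  eps <- rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + eps[i]
  x
}

#' Simulate a ground-truth sway trajectory
#'
#' Exact-discretization OU process per axis at the master rate (the least
#' common multiple of the two device rates), band-limited by the zero-phase
#' low-pass at `sway_bandwidth_hz`, covering the recording duration plus the
#' device lag. Reproducible under `seed`.
#'
#' @param scfg A [sway_sim_config()].
#' @param seed Optional integer seed (set once; omit to continue the current
#'   RNG stream).
#' @return A [cop_trajectory()] at the master rate (ground-truth COP).
#' @export
simulate_sway <- function(scfg = sway_sim_config(), seed = NULL) {
  stopifnot(inherits(scfg, "sway_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  master <- .master_rate(scfg)
  n <- as.integer(ceiling((scfg$duration_s + scfg$device_lag_s) * master)) + 1L
  dt <- 1 / master
  ml <- .ou_series(n, dt, scfg$sd_ml_cm, scfg$tau_ml_s)
  ap <- .ou_series(n, dt, scfg$sd_ap_cm, scfg$tau_ap_s)
  if (scfg$sd_ml_cm > 0) ml <- lowpass_zero_phase(ml, master, scfg$sway_bandwidth_hz, 4)
  if (scfg$sd_ap_cm > 0) ap <- lowpass_zero_phase(ap, master, scfg$sway_bandwidth_hz, 4)
  traj <- cop_trajectory(ml, ap, master)
  attr(traj, "sim_config") <- scfg
  traj
}

# complementary high-pass built from the zero-phase low-pass
.highpass_noise <- function(n, sd, rate, corner_hz) {
  if (sd == 0 || n == 0L) return(numeric(n))
  eps <- rnorm(n, 0, sd)
  eps - lowpass_zero_phase(eps, rate, corner_hz, 4)
}

#' Render the two device recordings from a truth trajectory
#'
#' Inverse COP mapping: the subject's weight is distributed onto the four
#' corner sensors as `F/4 * (1 +/- u)(1 +/- v)` with `u`, `v` the COP in
#' units of the half-spans, which [cop_from_corner_forces()] inverts
#' exactly; the wrench channels carry the same truth through the moment
#' equations with the board's weight added to `fz`. The configured device
#' lag (board starts later), timestamp jitter, white channel noise and
#' broadband ML noise are then applied.
#'
#' @param truth A [simulate_sway()] trajectory at the master rate.
#' @param scfg The matching [sway_sim_config()].
#' @param seed Optional integer seed.
#' @return List with `index` (corner-board [raw_recording()]) and
#'   `reference` (wrench-plate [raw_recording()]).
#' @export
render_devices <- function(truth, scfg = attr(truth, "sim_config"), seed = NULL) {
  stopifnot(inherits(truth, "cop_trajectory"), inherits(scfg, "sway_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  master <- truth$rate
  if (max(abs(truth$ml)) > scfg$span_ml_cm / 2 || max(abs(truth$ap)) > scfg$span_ap_cm / 2) {
    stop_coptools("truth COP lies outside the sensor span", "parameter_error")
  }
  w_sub <- scfg$subject_mass_kg * scfg$gravity

  pick <- function(rate, t0_s) {
    ratio <- as.integer(round(master / rate))
    n_dev <- as.integer(round(scfg$duration_s * rate)) + 1L
    start <- as.integer(round(t0_s * master)) + 1L
    idx <- seq.int(start, by = ratio, length.out = n_dev)
    if (idx[n_dev] > length(truth$ml)) {
      stop_coptools("truth trajectory does not cover duration + lag", "parameter_error")
    }
    idx
  }
  jittered_time <- function(t0_s, n, rate, jitter_ms) {
    base <- 1 / rate
    if (jitter_ms <= 0) return(t0_s + (seq_len(n) - 1L) * base)
    iv <- base + rnorm(n - 1L, 0, jitter_ms / 1000)
    iv <- pmax(iv, base / 4)
    t0_s + cumsum(c(0, iv))
  }

  # index device: corner board, starts device_lag_s later
  bi <- pick(scfg$rate_board_hz, scfg$device_lag_s)
  u <- truth$ml[bi] / (scfg$span_ml_cm / 2)
  v <- truth$ap[bi] / (scfg$span_ap_cm / 2)
  nb <- length(bi)
  ch <- list(tl = w_sub / 4 * (1 - u) * (1 + v),
             tr = w_sub / 4 * (1 + u) * (1 + v),
             bl = w_sub / 4 * (1 - u) * (1 - v),
             br = w_sub / 4 * (1 + u) * (1 - v))
  if (scfg$noise_board_n > 0) {
    ch <- lapply(ch, function(x) x + rnorm(nb, 0, scfg$noise_board_n))
  }
  if (scfg$ml_noise_board_n > 0) {
    eps <- .highpass_noise(nb, scfg$ml_noise_board_n, scfg$rate_board_hz,
                           scfg$ml_noise_corner_hz)
    ch$tr <- ch$tr + eps / 2; ch$br <- ch$br + eps / 2
    ch$tl <- ch$tl - eps / 2; ch$bl <- ch$bl - eps / 2
  }
  board <- raw_recording("corner_board",
                         jittered_time(0, nb, scfg$rate_board_hz, scfg$jitter_board_ms),
                         ch, scfg$rate_board_hz)

  # reference device: wrench plate, starts at t = 0, carries the board too
  pi_ <- pick(scfg$rate_plate_hz, 0)
  np <- length(pi_)
  ml_m <- truth$ml[pi_] / 100
  ap_m <- truth$ap[pi_] / 100
  wch <- list(fx = numeric(np), fy = numeric(np),
              fz = rep(w_sub + scfg$board_mass_kg * scfg$gravity, np),
              mx = ap_m * w_sub, my = -ml_m * w_sub, mz = numeric(np))
  if (scfg$noise_plate_n > 0) {
    wch <- lapply(wch, function(x) x + rnorm(np, 0, scfg$noise_plate_n))
  }
  plate <- raw_recording("wrench_plate",
                         jittered_time(0, np, scfg$rate_plate_hz, scfg$jitter_plate_ms),
                         wch, scfg$rate_plate_hz)
  list(index = board, reference = plate)
}

#' Simulate one dual-device trial
#'
#' Convenience wrapper: [simulate_sway()] then [render_devices()] under one
#' seed.
#'
#' @param scfg A [sway_sim_config()].
#' @param seed Optional integer seed.
#' @return List `truth`, `index`, `reference`.
#' @export
simulate_trial <- function(scfg = sway_sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_sway(scfg)
  dev <- render_devices(truth, scfg)
  list(truth = truth, index = dev$index, reference = dev$reference)
}

#' Simulate a test-retest cohort with known variance components
#'
#' Each subject i in session j sways with both axis SDs scaled by
#' `m_ij = 1 + a_i + e_ij`, `a_i ~ N(0, between_sd^2)` (stable subject
#' trait) and `e_ij ~ N(0, within_sd^2)` (session-to-session change). The
#' ground-truth scale factor therefore has intraclass correlation
#' `between_sd^2 / (between_sd^2 + within_sd^2)`, which propagates to the
#' SD-type sway metrics.
#'
#' @param n_subjects,k_sessions Cohort size (both >= 2).
#' @param between_sd,within_sd SDs of the subject and session effects on the
#'   sway-scale factor (>= 0, not both 0).
#' @param scfg Base [sway_sim_config()].
#' @param seed Optional integer seed (all randomness flows from it).
#' @param render If `TRUE`, device recordings are rendered for every
#'   subject-session (costly); otherwise only configurations and ground
#'   truth are returned.
#' @return List: `truth` (data frame subject, session, scale and true axis
#'   SDs), `true_icc`, `configs` (nested list of per-trial
#'   [sway_sim_config()]s), and `recordings` (nested list from
#'   [simulate_trial()]) when rendered.
#' @export
simulate_cohort <- function(n_subjects, k_sessions = 2, between_sd = 0.25,
                            within_sd = 0.05, scfg = sway_sim_config(),
                            seed = NULL, render = FALSE) {
  if (n_subjects < 2L || k_sessions < 2L) {
    stop_coptools("need at least 2 subjects and 2 sessions", "parameter_error")
  }
  if (between_sd < 0 || within_sd < 0 || (between_sd == 0 && within_sd == 0)) {
    stop_coptools("variance components must be >= 0 and not both 0", "parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  a <- rnorm(n_subjects, 0, between_sd)
  e <- matrix(rnorm(n_subjects * k_sessions, 0, within_sd), n_subjects, k_sessions)
  scale <- 1 + outer(a, rep(1, k_sessions)) + e
  scale[scale < 0.2] <- 0.2            # keep sway SDs physically positive
  truth <- data.frame(subject = rep(seq_len(n_subjects), k_sessions),
                      session = rep(seq_len(k_sessions), each = n_subjects),
                      scale = as.vector(scale))
  truth$sd_ml_true <- truth$scale * scfg$sd_ml_cm
  truth$sd_ap_true <- truth$scale * scfg$sd_ap_cm
  configs <- lapply(seq_len(n_subjects), function(i) {
    lapply(seq_len(k_sessions), function(j) {
      sc <- scfg
      sc$sd_ml_cm <- scfg$sd_ml_cm * scale[i, j]
      sc$sd_ap_cm <- scfg$sd_ap_cm * scale[i, j]
      sc
    })
  })
  recordings <- NULL
  if (render) {
    recordings <- lapply(seq_len(n_subjects), function(i) {
      lapply(seq_len(k_sessions), function(j) simulate_trial(configs[[i]][[j]]))
    })
  }
  list(truth = truth, true_icc = between_sd^2 / (between_sd^2 + within_sd^2),
       configs = configs, recordings = recordings)
}
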