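test_that("sway simulator is stationary, seeded and degenerate-safe", {
  still <- simulate_sway(clean_sim_config(sd_ml_cm = 0, sd_ap_cm = 0,
                                          duration_s = 5), seed = 1)
  expect_equal(still$ml, rep(0, n_samples(still)))
  expect_equal(still$ap, rep(0, n_samples(still)))

  a <- simulate_sway(sway_sim_config(duration_s = 5), seed = 42)
  b <- simulate_sway(sway_sim_config(duration_s = 5), seed = 42)
  expect_identical(a$ml, b$ml)
  expect_identical(a$ap, b$ap)
  c2 <- simulate_sway(sway_sim_config(duration_s = 5), seed = 43)
  expect_false(identical(a$ml, c2$ml))

  expect_error(sway_sim_config(tau_ml_s = 0), class = "coptools_parameter_error")
  expect_error(sway_sim_config(sd_ml_cm = -1), class = "coptools_parameter_error")
})

test_that("noise-free rendering inverts the COP formulas", {
  scfg <- clean_sim_config(duration_s = 10)
  tr <- simulate_trial(scfg, seed = 81)
  cfg <- run_config()
  ci <- compute_cop(tr$index, cfg)
  cr <- compute_cop(tr$reference, cfg)
  truth40 <- decimate_trajectory(tr$truth, 40)
  truth100 <- decimate_trajectory(tr$truth, 100)
  rms <- function(z) sqrt(mean(z^2))
  expect_lt(rms(ci$ml - truth40$ml[seq_along(ci$ml)]), 0.01)
  expect_lt(rms(ci$ap - truth40$ap[seq_along(ci$ap)]), 0.01)
  expect_lt(rms(cr$ml - truth100$ml[seq_along(cr$ml)]), 0.01)
  expect_lt(rms(cr$ap - truth100$ap[seq_along(cr$ap)]), 0.01)
})

test_that("the injected device lag is recoverable at the common rate", {
  scfg <- clean_sim_config(device_lag_s = 0.65, duration_s = 20)
  tr <- simulate_trial(scfg, seed = 82)
  cfg <- run_config()
  a <- downsample(lowpass_zero_phase(tr$index$channels$bl, 40, 10, 4), 40, 20)
  virt <- coptools:::.matching_series(tr$reference, cfg)
  b <- downsample(lowpass_zero_phase(virt, 100, 10, 4), 100, 20)
  # reference started 0.65 s earlier: 13 samples at 20 Hz
  expect_identical(as.integer(estimate_lag(a, b, 100)), -13L)
})

test_that("rendered timestamps carry the configured jitter", {
  scfg <- sway_sim_config(jitter_board_ms = 1, jitter_plate_ms = 0,
                          duration_s = 20)
  tr <- simulate_trial(scfg, seed = 83)
  expect_equal(sd(diff(tr$index$timestamps)) * 1000, 1, tolerance = 0.25)
  expect_equal(sd(diff(tr$reference$timestamps)), 0)
})

test_that("cohort simulation encodes the requested variance components", {
  expect_error(simulate_cohort(1, 2), class = "coptools_parameter_error")
  expect_error(simulate_cohort(10, 2, between_sd = 0, within_sd = 0),
               class = "coptools_parameter_error")

  co <- simulate_cohort(8, 2, between_sd = 0.3, within_sd = 0.1, seed = 84)
  expect_equal(co$true_icc, 0.09 / 0.10)
  expect_equal(nrow(co$truth), 16)
  expect_null(co$recordings)
  # per-trial configs carry the scaled sway SDs
  expect_equal(co$configs[[1]][[1]]$sd_ml_cm / sway_sim_config()$sd_ml_cm,
               co$truth$scale[co$truth$subject == 1 & co$truth$session == 1])

  # zero within-subject variance: the pipeline's session-to-session ICC is
  # near 1 for pathlength (whose finite-segment estimation noise is small)
  base <- clean_sim_config(duration_s = 24)
  co2 <- simulate_cohort(6, 2, between_sd = 0.45, within_sd = 0, scfg = base,
                         seed = 85, render = TRUE)
  cfg <- run_config()
  pl <- matrix(NA_real_, 6, 2)
  for (i in 1:6) for (j in 1:2) {
    trial <- co2$recordings[[i]][[j]]
    pp <- preprocess_recordings(trial$index, trial$reference, "bipedal", cfg)
    m <- compute_sway_metrics(compute_cop(pp$index, cfg), NULL, cfg)
    pl[i, j] <- m$pathlength_cm
  }
  expect_gt(icc(pl, "oneway")$estimate, 0.9)
})
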