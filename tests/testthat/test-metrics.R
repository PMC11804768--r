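test_that("displacement SD, velocity and pathlength match closed forms", {
  expect_equal(sd_displacement(rep(2, 10)), 0)
  expect_equal(sd_displacement(c(0, 2)), sqrt(2))
  expect_equal(sd_displacement(c(-1, 0, 1)), 1)
  expect_error(sd_displacement(1), class = "coptools_parameter_error")

  expect_equal(mean_velocity(rep(1, 10), 20), 0)
  expect_equal(mean_velocity(c(0, 1, 0, 1), 20), 3 / 0.15)   # 20 cm/s
  ramp <- seq(0, 5, by = 1 / 40)                              # slope 1 cm/s
  expect_equal(mean_velocity(ramp, 40), 1, tolerance = 1e-12)

  expect_equal(path_length(rep(0, 5), rep(0, 5)), 0)
  expect_equal(path_length(c(0, 3), c(0, 4)), 5)
  th <- seq(0, 2 * pi, length.out = 361)
  expect_equal(path_length(cos(th), sin(th)), 2 * pi, tolerance = 1e-3)
  expect_error(path_length(1:3, 1:4), class = "coptools_parameter_error")
})

test_that("prediction ellipse area uses the small-sample F factor", {
  # factor approaches the chi-square limit from above
  expect_equal(prediction_ellipse_factor(400) / 5.991465, 1.0, tolerance = 0.02)
  expect_gt(prediction_ellipse_factor(400), 5.991465)
  expect_gt(prediction_ellipse_factor(20), prediction_ellipse_factor(400))

  # large-n standard bivariate normal: area -> pi * chisq_0.95(2) = 18.82 cm^2
  set.seed(52)
  expect_equal(prediction_ellipse_area_95(rnorm(1e5), rnorm(1e5)), 18.82,
               tolerance = 0.3 / 18.82)

  expect_warning(a0 <- prediction_ellipse_area_95(rep(1, 10), rnorm(10)),
                 class = "coptools_degenerate_warning")
  expect_equal(a0, 0)
})

test_that("metric invariances hold on random trajectories", {
  set.seed(53)
  for (rep_i in 1:10) {
    ml <- cumsum(rnorm(200, 0, 0.05))
    ap <- cumsum(rnorm(200, 0, 0.05))
    traj <- cop_trajectory(ml, ap, 20)
    m0 <- compute_sway_metrics(traj)

    # translation invariance of all six metrics
    m_t <- compute_sway_metrics(cop_trajectory(ml + 3.7, ap - 1.2, 20))
    expect_equal(unclass(m_t), unclass(m0), tolerance = 1e-9)

    # rotation invariance of pathlength and PEA
    th <- runif(1, 0, 2 * pi)
    m_r <- compute_sway_metrics(cop_trajectory(cos(th) * ml - sin(th) * ap,
                                               sin(th) * ml + cos(th) * ap, 20))
    expect_equal(m_r$pathlength_cm, m0$pathlength_cm, tolerance = 1e-9)
    expect_equal(m_r$pea95_cm2, m0$pea95_cm2, tolerance = 1e-9)

    # triangle inequality: Euclidean path dominates each per-axis total
    expect_gte(m0$pathlength_cm, sum(abs(diff(ml))) - 1e-12)
    expect_gte(m0$pathlength_cm, sum(abs(diff(ap))) - 1e-12)
  }
})

test_that("compute_sway_metrics composes the individual operations", {
  set.seed(54)
  ml <- cumsum(rnorm(900, 0, 0.03))
  ap <- cumsum(rnorm(900, 0, 0.03))
  traj <- cop_trajectory(ml, ap, 40)
  cfg <- run_config()
  seg <- select_segment(900, 40, "bipedal", onset = 1L, cfg)
  m <- compute_sway_metrics(traj, seg, cfg)
  i <- seg$start:(seg$start + seg$length - 1)
  expect_identical(m$segment_rate_hz, 40)
  expect_equal(m$sd_ml_cm, sd_displacement(ml[i]))
  expect_equal(m$sd_ap_cm, sd_displacement(ap[i]))
  expect_equal(m$v_ml_cm_s, mean_velocity(ml[i], 40))
  expect_equal(m$v_ap_cm_s, mean_velocity(ap[i], 40))
  expect_equal(m$pathlength_cm, path_length(ml[i], ap[i]))
  # PEA comes from the 20 Hz decimated segment
  expect_equal(m$pea95_cm2,
               prediction_ellipse_area_95(downsample(ml[i], 40, 20),
                                          downsample(ap[i], 40, 20)))

  still <- compute_sway_metrics(cop_trajectory(rep(1, 500), rep(-2, 500), 20),
                                NULL, cfg) |> suppressWarnings()
  expect_equal(still$sd_ml_cm, 0)
  expect_equal(still$v_ap_cm_s, 0)
  expect_equal(still$pathlength_cm, 0)
  expect_equal(still$pea95_cm2, 0)
})

test_that("segment SD estimates the OU stationary SD", {
  # 20 s x 20 Hz windows: the median estimate over seeds sits within 10 % of
  # the configured stationary SD
  est <- numeric(100)
  for (s in 1:100) {
    scfg <- clean_sim_config(sd_ml_cm = 0.4, sd_ap_cm = 0.4, duration_s = 20,
                             rate_board_hz = 20, rate_plate_hz = 20)
    traj <- simulate_sway(scfg, seed = 1000 + s)
    est[s] <- sd_displacement(traj$ml[1:401])
  }
  expect_gte(median(est), 0.34)
  expect_lte(median(est), 0.46)
})
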