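test_that("mean squares equal an independent aov decomposition", {
  m0 <- rbind(c(1, 1), c(2, 2), c(3, 3))
  ms0 <- anova_mean_squares(m0)
  expect_equal(ms0$mse, 0)
  expect_equal(ms0$msw, 0)

  set.seed(71)
  for (rep_i in 1:20) {
    n <- sample(3:20, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 10, 3), n, k)
    ours <- anova_mean_squares(m)
    ref <- aov_mean_squares(m)
    expect_equal(ours$msr, ref$msr, tolerance = 1e-10)
    expect_equal(ours$msw, ref$msw, tolerance = 1e-10)
    expect_equal(ours$msc, ref$msc, tolerance = 1e-10)
    expect_equal(ours$mse, ref$mse, tolerance = 1e-10)

    # a constant added to one column moves the column and within-row terms
    # but leaves the row and interaction structure untouched
    m2 <- m; m2[, 1] <- m2[, 1] + 5
    ms2 <- anova_mean_squares(m2)
    expect_equal(ms2$msr, ours$msr, tolerance = 1e-9)
    expect_equal(ms2$mse, ours$mse, tolerance = 1e-9)
    expect_false(isTRUE(all.equal(ms2$msc, ours$msc)))
    expect_false(isTRUE(all.equal(ms2$msw, ours$msw)))
  }
})

test_that("the three ICC forms behave as the models predict", {
  # perfectly repeated sessions with between-subject spread: all ICCs are 1
  perf <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  for (kind in c("oneway", "agreement", "consistency")) {
    expect_equal(icc(perf, kind)$estimate, 1)
  }

  # constant bias, zero residual: consistency 1, agreement = v / (v + b^2/2)
  set.seed(72)
  x <- rnorm(12, 10, 2); b <- 1.5
  biased <- cbind(x, x + b)
  expect_equal(icc(biased, "consistency")$estimate, 1)
  expect_equal(icc(biased, "agreement")$estimate,
               var(x) / (var(x) + b^2 / 2), tolerance = 1e-10)
  expect_lt(icc(biased, "agreement")$estimate, 1)

  # estimate always inside its CI; estimate <= 1
  for (rep_i in 1:10) {
    m <- random_effects_matrix(12, 2, 1, 0.3, 0.5)
    for (kind in c("oneway", "agreement", "consistency")) {
      r <- icc(m, kind)
      expect_lte(r$estimate, 1)
      expect_lte(r$ci95_low, r$estimate + 1e-12)
      expect_gte(r$ci95_high, r$estimate - 1e-12)
    }
  }

  # degenerate matrix is flagged, not mis-estimated
  d <- icc(matrix(2, 4, 2), "oneway")
  expect_true(d$degenerate)
  expect_true(is.na(d$estimate))
})

test_that("ICC formulas agree with the aov-mean-square route to 1e-10", {
  set.seed(73)
  for (rep_i in 1:25) {
    n <- sample(3:30, 1); k <- sample(2:4, 1)
    m <- random_effects_matrix(n, k, runif(1, 0.5, 2), runif(1, 0, 0.5),
                               runif(1, 0.2, 1))
    ref <- aov_mean_squares(m)
    expect_equal(icc(m, "oneway")$estimate,
                 (ref$msr - ref$msw) / (ref$msr + (k - 1) * ref$msw),
                 tolerance = 1e-10)
    expect_equal(icc(m, "consistency")$estimate,
                 (ref$msr - ref$mse) / (ref$msr + (k - 1) * ref$mse),
                 tolerance = 1e-10)
    expect_equal(icc(m, "agreement")$estimate,
                 (ref$msr - ref$mse) /
                   (ref$msr + (k - 1) * ref$mse + (k / n) * (ref$msc - ref$mse)),
                 tolerance = 1e-10)
  }
})

test_that("SEM and MDC follow their defining identities", {
  sm <- sem_mdc(1, 0.75)
  expect_equal(sm$sem, 0.5)
  expect_equal(sm$mdc, 0.5 * 1.96 * sqrt(2))
  expect_equal(sm$mdc, 1.38593, tolerance = 1e-5)

  expect_equal(sem_mdc(3, 1), list(sem = 0, mdc = 0))
  expect_error(sem_mdc(1, 1.2), class = "coptools_parameter_error")
  expect_error(sem_mdc(-1, 0.5), class = "coptools_parameter_error")
  expect_warning(neg <- sem_mdc(1, -0.2), class = "coptools_clinimetrics_warning")
  expect_equal(neg$sem, sqrt(1.2))

  # mdc / sem is exactly 1.96 * sqrt(2) whatever the inputs
  set.seed(74)
  for (rep_i in 1:20) {
    sm_i <- sem_mdc(runif(1, 0, 10), runif(1, 0, 1))
    if (sm_i$sem > 0) expect_equal(sm_i$mdc / sm_i$sem, 1.96 * sqrt(2))
  }
})

test_that("device agreement statistics are computed pairwise", {
  a <- agreement(c(10, 10), c(8, 8))
  expect_equal(a$absolute$mean, 2)
  expect_equal(a$relative$mean_pct, 20)

  set.seed(75)
  ref <- runif(20, 5, 30)
  z <- agreement(ref, ref)
  expect_equal(z$absolute$mean, 0)
  expect_equal(z$absolute$sd, 0)
  expect_equal(z$relative$mean_pct, 0)
  expect_equal(z$relative$sd_pct, 0)

  # near-zero reference values are excluded from the relative part only
  e <- agreement(c(10, 1e-9, 20), c(9, 5, 18))
  expect_equal(e$absolute$n, 3)
  expect_equal(e$relative$n, 2)
  expect_equal(e$relative$n_excluded, 1)

  expect_error(agreement(1:3, 1:4), class = "coptools_parameter_error")
})

test_that("the discrepancy gate reports one-way only for marginal differences", {
  as_iccs <- function(v) list(oneway = list(estimate = v[1]),
                              agreement = list(estimate = v[2]),
                              consistency = list(estimate = v[3]))
  g1 <- icc_discrepancy_gate(as_iccs(c(0.731, 0.733, 0.734)))
  expect_identical(g1$report, "oneway")
  expect_false(g1$bias_flag)

  g2 <- icc_discrepancy_gate(as_iccs(c(0.60, 0.75, 0.76)))
  expect_identical(g2$report, "two_way_forms")
  expect_true(g2$bias_flag)

  g3 <- icc_discrepancy_gate(as_iccs(rep(0.5, 3)))
  expect_identical(g3$report, "oneway")
})

test_that("reliability and validity reports assemble the pieces coherently", {
  set.seed(76)
  mats <- list(pathlength_cm = random_effects_matrix(25, 2, 4, 0.2, 2),
               sd_ap_cm = random_effects_matrix(25, 2, 0.1, 0.01, 0.08))
  rep <- reliability_report(mats)
  for (nm in names(rep)) {
    r <- rep[[nm]]
    expect_equal(r$mdc / r$sem, 1.96 * sqrt(2))
    expect_equal(r$pooled_sd, sd(as.vector(mats[[nm]])))
  }
  r1 <- rep$pathlength_cm
  expect_equal(r1$pooled_sd, sd(as.vector(mats$pathlength_cm)))
  expect_equal(r1$sem, r1$pooled_sd * sqrt(1 - r1$icc[[r1$primary_kind]]$estimate))

  # incomplete subjects are dropped listwise and counted
  m_na <- mats$pathlength_cm
  m_na[3, 2] <- NA
  rep_na <- reliability_report(list(pathlength_cm = m_na))
  expect_equal(rep_na$pathlength_cm$n, 24)
  expect_equal(rep_na$pathlength_cm$n_dropped, 1)

  v <- validity_report(list(pathlength_cm = mats$pathlength_cm[, 1] + rnorm(25, 0, 0.5)),
                       list(pathlength_cm = mats$pathlength_cm[, 1]))
  expect_s3_class(v$pathlength_cm$icc_a1, "icc_result")
  expect_identical(v$pathlength_cm$icc_a1$kind, "agreement")
  expect_gt(v$pathlength_cm$icc_a1$estimate, 0.9)
})

test_that("ICC confidence intervals admit negative lower bounds", {
  # strong session bias with little subject spread drives ICC(A,1) down and
  # its CI below zero, as reported (never truncated)
  set.seed(77)
  x <- rnorm(10, 0, 0.3)
  m <- cbind(x, x + 2 + rnorm(10, 0, 0.2))
  r <- icc(m, "agreement")
  expect_lt(r$ci95_low, 0)
  expect_lt(r$estimate, 0.5)
})
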