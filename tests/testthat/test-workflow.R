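test_that("simulate -> cop -> metrics -> psd workflow chain runs end to end", {
  dir <- withr::local_tempdir()
  sim <- run_workflow("simulate", list(out_dir = file.path(dir, "fix"),
                                       seed = 91, duration_s = 30))
  expect_identical(sim$status, 0L)
  expect_true(all(file.exists(unlist(sim$outputs))))
  expect_true(file.exists(sim$manifest))

  cop_out <- file.path(dir, "cop.csv")
  cop <- run_workflow("cop", list(input = sim$outputs$index, device = "corner_board",
                                  out = cop_out))
  expect_identical(cop$status, 0L)

  met <- run_workflow("metrics", list(cop = cop_out,
                                      out = file.path(dir, "metrics.json")))
  expect_identical(met$status, 0L)
  m <- jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
  expect_named(m, c("sd_ml_cm", "sd_ap_cm", "v_ml_cm_s", "v_ap_cm_s",
                    "pathlength_cm", "pea95_cm2", "segment_rate_hz",
                    "segment_duration_s"), ignore.order = TRUE)
  expect_gt(m$pathlength_cm, 0)

  spec <- run_workflow("psd", list(cop_files = cop_out,
                                   out = file.path(dir, "spectra.json")))
  expect_identical(spec$status, 0L)
  s <- jsonlite::read_json(file.path(dir, "spectra.json"), simplifyVector = TRUE)
  expect_true(all(s$power_ml_cm2_hz >= 0))

  # the manifest digests every output it names
  man <- jsonlite::read_json(sim$manifest, simplifyVector = TRUE)
  expect_true(all(nchar(unlist(man$outputs)) == 32))
  expect_equal(man$seed, 91)
})

test_that("workflows are deterministic and never mutate inputs", {
  dir <- withr::local_tempdir()
  a <- run_workflow("simulate", list(out_dir = file.path(dir, "a"), seed = 7))
  b <- run_workflow("simulate", list(out_dir = file.path(dir, "b"), seed = 7))
  expect_identical(readLines(a$outputs$index), readLines(b$outputs$index))
  expect_identical(readLines(a$outputs$reference), readLines(b$outputs$reference))

  digest_before <- tools::md5sum(a$outputs$index)
  cop <- run_workflow("cop", list(input = a$outputs$index, device = "corner_board",
                                  out = file.path(dir, "c1.csv")))
  expect_identical(cop$status, 0L)
  expect_identical(tools::md5sum(a$outputs$index), digest_before)

  cop2 <- run_workflow("cop", list(input = b$outputs$index, device = "corner_board",
                                   out = file.path(dir, "c2.csv")))
  expect_identical(readLines(file.path(dir, "c1.csv")),
                   readLines(file.path(dir, "c2.csv")))
})

test_that("usage errors exit 2 and computational errors exit 1", {
  miss <- run_workflow("cop", list(input = "does_not_exist.csv",
                                   device = "corner_board", out = "x.csv"))
  expect_identical(miss$status, 2L)
  expect_match(miss$error, "not found")

  unknown <- run_workflow("frobnicate", list())
  expect_identical(unknown$status, 2L)

  bad_args <- run_workflow("metrics", list())
  expect_identical(bad_args$status, 2L)

  # unloaded plate is a computational failure, not a usage one
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty_board.csv")
  write_recording(p, make_corner_rec(1, 1, 1, 1, rate = 40))
  res <- run_workflow("cop", list(input = p, device = "corner_board",
                                  out = file.path(dir, "c.csv")))
  expect_identical(res$status, 1L)
  expect_match(res$error, "floor")
})

test_that("calibrate and reliability/validity workflows produce their reports", {
  dir <- withr::local_tempdir()
  zero_p <- file.path(dir, "zero.csv"); load_p <- file.path(dir, "load.csv")
  write_recording(zero_p, make_corner_rec(rep(100, 200), rep(101, 200),
                                          rep(99, 200), rep(100, 200), rate = 5))
  write_recording(load_p, make_corner_rec(rep(200, 200), rep(201, 200),
                                          rep(199, 200), rep(200, 200), rate = 5))
  cal <- run_workflow("calibrate", list(zero = zero_p, load = load_p, mass = 55,
                                        out = file.path(dir, "cal.json")))
  expect_identical(cal$status, 0L)
  model <- read_calibration(file.path(dir, "cal.json"))
  expect_equal(unname(model$gain["tl"]), 55 * 9.81 / 4 / 100, tolerance = 1e-9)

  set.seed(92)
  s1 <- list(pathlength_cm = rnorm(20, 22, 5))
  s2 <- list(pathlength_cm = s1$pathlength_cm + rnorm(20, 0, 2))
  f1 <- file.path(dir, "s1.json"); f2 <- file.path(dir, "s2.json")
  jsonlite::write_json(s1, f1, digits = NA); jsonlite::write_json(s2, f2, digits = NA)
  rel <- run_workflow("reliability", list(session1 = f1, session2 = f2,
                                          out = file.path(dir, "rel.json")))
  expect_identical(rel$status, 0L)
  rep <- jsonlite::read_json(file.path(dir, "rel.json"), simplifyVector = TRUE)
  expect_equal(rep$metrics$pathlength_cm$mdc / rep$metrics$pathlength_cm$sem,
               1.96 * sqrt(2), tolerance = 1e-12)

  val <- run_workflow("validity", list(index = f1, reference = f2,
                                       out = file.path(dir, "val.json")))
  expect_identical(val$status, 0L)
  vrep <- jsonlite::read_json(file.path(dir, "val.json"), simplifyVector = TRUE)
  expect_identical(vrep$metrics$pathlength_cm$icc_a1$kind, "agreement")
})
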