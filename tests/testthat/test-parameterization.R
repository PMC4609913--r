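test_that("release rate conversion matches dimensional analysis", {
  # 1 ng/mL net over background, 500 uL, 1.5e6 cells, 24 h, 10 kDa:
  # 0.5 ng -> 0.5e-9/1e4 mol -> 3.011e10 molecules over 1.5e6 cells
  # and 1440 min = 13.94 molecules/cell/min
  m <- supernatant_measurement(1.05, 0.05, 0.5, 1.5e6, 24, blockade = TRUE)
  r <- release_rate_from_supernatant(m, 10)
  oracle <- 0.5e-9 / (10 * 1000) * 6.02214076e23 / (1.5e6 * 24 * 60)
  expect_equal(as.numeric(r), oracle, tolerance = 1e-12)
  expect_false(attr(r, "clamped"))
  expect_true(is.na(attr(r, "warning")))
})

test_that("release rate clamps negatives and flags capture confound", {
  m_eq <- supernatant_measurement(0.05, 0.05, 0.5, 1e6, 24, blockade = TRUE)
  expect_equal(as.numeric(release_rate_from_supernatant(m_eq, 10)), 0)
  expect_false(attr(release_rate_from_supernatant(m_eq, 10), "clamped"))

  m_neg <- supernatant_measurement(0.01, 0.05, 0.5, 1e6, 24, blockade = TRUE)
  r <- release_rate_from_supernatant(m_neg, 10)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))

  m_open <- supernatant_measurement(1, 0.05, 0.5, 1e6, 24, blockade = FALSE)
  expect_match(attr(release_rate_from_supernatant(m_open, 10), "warning"),
               "capture confound")
  expect_error(supernatant_measurement(1, NULL, 0.5, 1e6, 24),
               "background")
})

test_that("capture ratio arithmetic, clipping and errors", {
  mk <- function(conc, blockade) supernatant_measurement(
    conc, 0.5, 0.5, 1e6, 24, blockade = blockade)
  expect_equal(as.numeric(capture_ratio(mk(8.5, FALSE), mk(8.5, TRUE))), 1)
  expect_equal(as.numeric(capture_ratio(mk(0.5, FALSE), mk(8.5, TRUE))), 0)
  expect_equal(as.numeric(capture_ratio(mk(2.5, FALSE), mk(8.5, TRUE))),
               0.25)
  clipped <- capture_ratio(mk(10, FALSE), mk(8.5, TRUE))
  expect_equal(as.numeric(clipped), 1)
  expect_true(attr(clipped, "clipped"))
  expect_error(capture_ratio(mk(2, FALSE), mk(0.4, TRUE)), "> 0")
})

test_that("receptor calibration interpolates exactly and flags range", {
  curve <- calibration_curve(signal = c(10, 20, 40, 80, 160),
                             known = c(1e4, 2e4, 4e4, 8e4, 16e4))
  # exact at a calibration point
  expect_equal(as.numeric(receptor_count_from_calibration(40, curve)), 4e4)
  # midway between two points on a linear curve -> mean of the knowns
  expect_equal(as.numeric(receptor_count_from_calibration(30, curve)), 3e4)
  over <- receptor_count_from_calibration(320, curve)
  expect_true(attr(over, "extrapolated"))
  expect_equal(as.numeric(over), 32e4)
  expect_error(calibration_curve(c(10, 5, 40), c(1, 2, 3)), "monoton")
})

test_that("release rate round-trips through a blocked 24 h simulation", {
  sys <- tiny_system(Q = 25)
  exp1 <- gen_capture_experiment(sys, noise_cv = 0)
  r <- release_rate_from_supernatant(exp1$blocked,
                                     sys$ligands$HBEGF$mw_kDa)
  expect_equal(as.numeric(r), 25, tolerance = 0.01)
})

test_that("calibrate_system recovers K_D from synthetic observables", {
  sys_true <- tiny_system(K_D_nM = 3, Q = 15)
  exp1 <- gen_capture_experiment(sys_true, noise_cv = 0)
  rate <- as.numeric(release_rate_from_supernatant(exp1$blocked, 10))
  ratio <- as.numeric(capture_ratio(exp1$unblocked, exp1$blocked))
  cal <- calibrate_system(c(HBEGF = rate),
                          receptor_count = 2e5,
                          capture_ratios = c(HBEGF = ratio),
                          config = default_config("HBEGF"))
  expect_lt(abs(log2(cal$ligands$HBEGF$K_D / 3e-9)), 1) # within 2-fold
  expect_true(all(attr(cal, "calibration")$ok))
  # model free fraction agrees with the measured ratio
  expect_lt(abs(free_ligand_fraction(cal, "HBEGF") - ratio), 0.05)
})

test_that("calibrate_system flags boundaries and missing rates", {
  cal <- calibrate_system(c(HBEGF = 10),
                          capture_ratios = c(HBEGF = 1.0),
                          config = default_config("HBEGF"),
                          kd_range = c(1e-11, 1e-6))
  expect_true(attr(cal, "calibration")$at_boundary)
  expect_equal(cal$ligands$HBEGF$K_D, 1e-6) # pinned to the top of range
  expect_error(calibrate_system(c(HBEGF = 10), config = default_config()),
               "AREG")
})
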