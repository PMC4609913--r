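test_that("initial rate estimates flat, linear and saturating series", {
  t5 <- 0:4
  expect_equal(as.numeric(initial_rate(t5, rep(3, 5))), 0)
  expect_equal(as.numeric(initial_rate(t5, 2 * t5 + 1)), 2)

  # saturating exponential F(t) = A(1 - exp(-t/tau)): initial slope A/tau
  tau <- 100; A <- 50
  tt <- seq(0, 40, by = 2)
  f <- A * (1 - exp(-tt / tau))
  sl <- initial_rate(tt, f, window = 0.1 * tau)
  expect_equal(as.numeric(sl), A / tau, tolerance = 0.05)
  # full window underestimates and shows curvature
  full <- initial_rate(tt, f)
  expect_lt(as.numeric(full), A / tau)
  expect_lt(attr(full, "curvature_t"), -2)
  expect_error(initial_rate(0:1, c(1, 2)), ">= 3")
})

test_that("noiseless hyperbolic data round-trips the generator IC50", {
  a <- gen_dose_response(430, "hyperbolic", noise_cv = 0, top_dose_nM = 1e4)
  f <- fit_inhibition(a, n_boot = 0)
  expect_equal(f$model, "hyperbolic")
  expect_equal(f$ic50, 430, tolerance = 1e-6)
  expect_equal(f$k_i, 430, tolerance = 1e-6)
  expect_false(f$km_corrected)
  # with a K_M correction the reported K_i shrinks by 1 + S/K_M
  fk <- fit_inhibition(a, K_M_uM = 15, n_boot = 0)
  expect_equal(fk$k_i, 430 / 2, tolerance = 1e-6)
  expect_true(fk$km_corrected)
})

test_that("tight-binding data needs the Morrison fit", {
  a <- gen_dose_response(2, "morrison", enzyme_conc_nM = 5,
                         top_dose_nM = 100, noise_cv = 0)
  f <- fit_inhibition(a, n_boot = 0)
  expect_equal(f$model, "tight-binding")
  expect_equal(f$k_i, 2, tolerance = 0.05)
  expect_lte(f$k_i, f$ic50) # depletion-corrected K_i below apparent IC50

  # a plain hyperbolic read of the same data is biased high
  hyp <- autoloop:::.morrison_frac(a$doses, 5, 2)
  bias <- stats::coef(minpack.lm::nlsLM(
    v ~ ic50 / (ic50 + I), data = data.frame(I = a$doses, v = hyp),
    start = list(ic50 = 10)))[["ic50"]]
  expect_gt(bias, 2 * 1.5)
})

test_that("hyperbolic and Morrison agree when depletion is negligible", {
  a <- gen_dose_response(1000, "hyperbolic", enzyme_conc_nM = 5,
                         top_dose_nM = 3e4, noise_cv = 0)
  hyp <- fit_inhibition(a, n_boot = 0)
  # force the tight-binding model on the same data
  df <- data.frame(I = a$doses, v = a$rates)
  mor <- stats::coef(minpack.lm::nlsLM(
    v ~ v0 * autoloop:::.morrison_frac(I, 5, ki), data = df,
    start = list(v0 = 1, ki = 500), lower = c(0, 1e-9)))
  expect_equal(unname(mor[["ki"]]) + 5 / 2, hyp$ic50, tolerance = 0.02)
})

test_that("flat dilution series yields a no-inhibition bound", {
  a <- gen_dose_response(1e9, "hyperbolic", noise_cv = 0,
                         top_dose_nM = 1e4)
  f <- fit_inhibition(a)
  expect_true(f$no_inhibition)
  expect_equal(f$k_i_lower_bound, 1e4)
  expect_true(is.na(f$ic50))
})

test_that("no false potency across noisy flat curves", {
  flagged <- sum(vapply(1:100, function(s) {
    a <- gen_dose_response(1e9, "hyperbolic", noise_cv = 0.05, seed = s,
                           top_dose_nM = 1e4)
    fit_inhibition(a, n_boot = 0)$no_inhibition
  }, logical(1)))
  expect_gte(flagged, 99)
})

test_that("noisy dilution series recover IC50 within 10% median error", {
  errs <- vapply(1:50, function(s) {
    a <- gen_dose_response(430, "hyperbolic", noise_cv = 0.05, seed = s,
                           top_dose_nM = 1e4, replicates = 2)
    abs(fit_inhibition(a, n_boot = 0)$ic50 - 430) / 430
  }, numeric(1))
  expect_lte(stats::median(errs), 0.10)
})

test_that("rising dose-velocity data raises a fit-quality error", {
  a <- inhibition_assay(c(0, 1, 10, 100, 1000), c(1, 1, 1.5, 1.6, 0.1))
  expect_error(fit_inhibition(a, n_boot = 0), "fit-quality")
})

test_that("bootstrap CIs bracket the generator value", {
  a <- gen_dose_response(430, "hyperbolic", noise_cv = 0.05, seed = 7,
                         top_dose_nM = 1e4)
  f <- fit_inhibition(a, n_boot = 100, seed = 11)
  expect_lt(f$ic50_ci[1], f$ic50_ci[2])
  expect_true(f$ic50_ci[1] <= 430 && 430 <= f$ic50_ci[2])
})

test_that("specificity panel propagates bounds as fold-selectivity", {
  hit <- fit_inhibition(gen_dose_response(430, "hyperbolic", noise_cv = 0,
                                          top_dose_nM = 1e4,
                                          enzyme = "ADAM12"), n_boot = 0)
  miss <- function(nm) fit_inhibition(
    gen_dose_response(1e9, "hyperbolic", noise_cv = 0, top_dose_nM = 1e4,
                      enzyme = nm), n_boot = 0)
  rep <- specificity_panel(list(hit, miss("ADAM10"), miss("ADAM17")))
  expect_equal(rep$selectivity$best, "ADAM12")
  expect_equal(rep$selectivity$qualifier, ">=")
  expect_equal(rep$selectivity$fold, 1e4 / 430, tolerance = 1e-6)

  all_miss <- specificity_panel(list(miss("a"), miss("b")))
  expect_null(all_miss$selectivity)
  expect_error(specificity_panel(list(hit)), ">= 2")
})
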