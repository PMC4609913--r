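make_panel <- function(series_by_rep, times) {
  # one condition, one substrate, series_by_rep: list of numeric vectors
  arr <- array(NA_real_, c(1, 1, length(series_by_rep), length(times)),
               dimnames = list("c1", "s1", NULL, NULL))
  for (r in seq_along(series_by_rep)) arr[1, 1, r, ] <- series_by_rep[[r]]
  fret_panel(arr, times)
}

test_that("cleavage rates recover exact and least-squares slopes", {
  times <- 0:4
  flat <- make_panel(list(rep(7, 5)), times)
  expect_equal(unname(cleavage_rates(flat)$rates[1, 1]), 0)

  line <- make_panel(list(0:4), times)
  expect_equal(unname(cleavage_rates(line)$rates[1, 1]), 1)

  noisy <- c(0.1, 0.9, 2.2, 2.8, 4.1)
  got <- cleavage_rates(make_panel(list(noisy), times))$rates[1, 1]
  xc <- times - mean(times) # closed-form OLS oracle
  expect_equal(unname(got), sum(xc * noisy) / sum(xc^2), tolerance = 1e-12)
})

test_that("replicates with too few finite points are dropped, not used", {
  times <- 0:4
  p <- make_panel(list(0:4, c(5, NA, NA, NA, NA)), times)
  expect_warning(cr <- cleavage_rates(p), "dropped")
  expect_equal(unname(cr$rates[1, 1]), 1)
  expect_equal(unname(cr$n[1, 1]), 1)
  bad <- make_panel(list(c(5, NA, NA, NA, 1), c(2, NA, NA, NA, NA)), times)
  # second replicate cannot support a slope; first still can
  expect_warning(cr2 <- cleavage_rates(bad), "dropped")
  expect_equal(unname(cr2$n[1, 1]), 1)
})

test_that("signature validation rejects indistinguishable proteases", {
  m <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("s1", "s2"), c("p1", "p2")))
  expect_error(signature_matrix(m), "indistinguishable")
})

test_that("NNLS solves identity and consistent systems exactly", {
  eye <- diag(4)
  dimnames(eye) <- list(paste0("s", 1:4), paste0("p", 1:4))
  sig <- signature_matrix(eye)
  # identity signature: activities are the rates
  rates <- matrix(1:4, 1, dimnames = list("c1", paste0("s", 1:4)))
  act <- infer_activities(rates, sig)
  expect_equal(unname(act$activities[1, ]), c(1, 2, 3, 4))

  sig2 <- example_signature()
  a_true <- c(ADAM8 = 0.4, ADAM10 = 1.3, ADAM12 = 0.05, ADAM17 = 2)
  r2 <- matrix(as.vector(sig2 %*% a_true), 1,
               dimnames = list("c1", rownames(sig2)))
  got <- infer_activities(r2, sig2)$activities[1, ]
  expect_equal(unname(got), unname(a_true), tolerance = 1e-6)
})

test_that("NNLS matches exhaustive grid search on small instances", {
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(runif(6, 0.1, 1), 3, 2,
                dimnames = list(paste0("s", 1:3), paste0("p", 1:2)))
    # include negative latent components so non-negativity binds sometimes
    a_lat <- runif(2, -0.5, 1.5)
    b <- as.vector(A %*% a_lat)
    got <- infer_activities(matrix(pmax(b, 0), 1,
                                   dimnames = list("c", rownames(A))),
                            signature_matrix(A))$activities[1, ]
    oracle <- brute_nnls(A, pmax(b, 0), upper = 2, res = 1e-3)
    expect_lt(max(abs(unname(got) - oracle)), 1.5e-3) # grid half-step slack
    if (any(a_lat < 0)) expect_true(any(got <= 1e-8))
  }
})

test_that("subset ensembling averages consistent solutions", {
  sig <- example_signature()
  truth <- csr_ground_truth(11)
  rates <- truth$activities %*% t(sig)
  ens <- infer_activities(rates, sig, ensemble = "subsets")
  # consistent (noise-free) system: every subset solves to the truth
  expect_equal(unname(ens$activities), unname(truth$activities),
               tolerance = 1e-6)
  expect_true(all(ens$dispersion < 1e-6))
})

test_that("response normalization arithmetic, clamping and errors", {
  raw <- matrix(c(10, 3), 1, 2,
                dimnames = list("c1", c("HBEGF", "TNFR1")))
  out <- normalize_responses(raw, c(c1 = 1e5), c(4, 4), volume_mL = 0.1)
  expect_equal(unname(out$responses[1, 1]), (10 - 4) * 0.1 / 1e5)
  expect_equal(unname(out$responses[1, 2]), 0) # clamped
  expect_true(out$clamped[1, 2])
  expect_error(normalize_responses(raw, c(zz = 1e5), c(4, 4)),
               "cell count")
  expect_error(normalize_responses(raw, c(c1 = 1e5), c(NA, 4)),
               "background")
})

test_that("Pearson r and p match the textbook formulas", {
  A <- matrix(c(1, 2, 3, 5), 4, 1, dimnames = list(paste0("c", 1:4), "P"))
  B <- matrix(c(2, 1, 4, 5), 4, 1, dimnames = list(paste0("c", 1:4), "S"))
  got <- correlate_csr(A, B)
  oracle <- hand_pearson(c(1, 2, 3, 5), c(2, 1, 4, 5))
  expect_equal(got$r[1, 1], oracle$r, tolerance = 1e-10)
  expect_equal(got$p[1, 1], oracle$p, tolerance = 1e-10)
  expect_equal(got$n[1, 1], 4)
})

test_that("correlation is affine-invariant and exact on copies", {
  set.seed(3)
  A <- matrix(runif(8), 8, 1, dimnames = list(paste0("c", 1:8), "P"))
  B <- A * 2 + 0.7
  colnames(B) <- "S"
  got <- correlate_csr(A, B)
  expect_equal(got$r[1, 1], 1, tolerance = 1e-12)
  expect_lt(got$p[1, 1], 1e-6)
  # rescaling either side leaves r unchanged
  g2 <- correlate_csr(A * 13.5, B)
  expect_equal(g2$r[1, 1], got$r[1, 1], tolerance = 1e-12)
})

test_that("zero-variance vectors give missing, not zero, correlations", {
  A <- matrix(c(1, 1, 1, 1), 4, 1, dimnames = list(paste0("c", 1:4), "P"))
  B <- matrix(c(2, 1, 4, 5), 4, 1, dimnames = list(paste0("c", 1:4), "S"))
  got <- correlate_csr(A, B)
  expect_true(is.na(got$r[1, 1]))
  expect_equal(got$n[1, 1], 4)
})

test_that("sheddase ranking orders by r with deterministic tie-breaks", {
  r <- matrix(c(0.9, 0.9, 0.2), 3, 1,
              dimnames = list(c("ADAM12", "ADAM10", "ADAM17"), "HBEGF"))
  p <- matrix(c(0.01, 0.001, 0.5), 3, 1, dimnames = dimnames(r))
  corr <- structure(list(r = r, p = p, n = r * 0 + 8),
                    class = "correlation_result")
  rk <- rank_sheddases(corr, "HBEGF")
  expect_equal(rk$protease, c("ADAM10", "ADAM12", "ADAM17")) # tie: lower p
  r2 <- r; p2 <- p; p2[1:2] <- 0.01
  corr2 <- structure(list(r = r2, p = p2, n = r * 0 + 8),
                     class = "correlation_result")
  expect_equal(rank_sheddases(corr2, "HBEGF")$protease[1], "ADAM10") # label
  expect_error(rank_sheddases(corr, "nope"), "unknown substrate")
})

test_that("dominant coupling is recovered end to end", {
  sig <- example_signature()
  truth <- csr_ground_truth(123, noise_cv = 0.1)
  p <- gen_fret_panel(truth, sig)
  shed <- gen_shedding_panel(truth)
  act <- infer_activities(cleavage_rates(p)$rates, sig)
  resp <- normalize_responses(shed$raw, shed$cells, shed$background,
                              shed$volume_mL)
  mab <- grep("_mab225$", rownames(truth$activities), value = TRUE)
  corr <- correlate_csr(act, resp, conditions = mab)
  expect_equal(rank_sheddases(corr, "HBEGF")$protease[1], "ADAM12")
  expect_equal(rank_sheddases(corr, "MET")$protease[1], "ADAM10")
})

test_that("signature CSV round-trips through the file reader", {
  path <- system.file("extdata", "example_signature_synthetic.csv",
                      package = "autoloop")
  sig <- read_signature_matrix(path)
  expect_equal(unclass(sig)[,], unclass(example_signature())[,])
})
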