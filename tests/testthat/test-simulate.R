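test_that("null source leaves every ligand state at zero", {
  sys <- tiny_system(Q = 0)
  tr <- simulate_system(sys, hours = 2)
  lig_cols <- grep("HBEGF", colnames(tr$state))
  expect_true(all(tr$state[, lig_cols] == 0))
  expect_error(capture_fraction(tr), "undefined")
})

test_that("decoy antibody is conserved when there are no sinks", {
  cfg <- default_config("HBEGF")
  cfg$ligands[[1]]$Q_molecules_cell_min <- 0
  cfg$receptor$R0 <- 0
  cfg$decoy <- default_decoy(dose_nM = 67)
  sys <- build_system(cfg)
  tr <- simulate_system(sys, hours = 24)
  g <- sys$geometry
  total_ab <- tr$state[, "AbS"] * g$V_S + tr$state[, "AbB"] * g$V_B +
    tr$state[, "AbBB"] * g$V_BB
  # total amount constant; diffusion only redistributes
  expect_equal(max(abs(total_ab - total_ab[1])) / total_ab[1], 0,
               tolerance = 1e-8)
  # and concentrations equilibrate toward the bulk dose
  expect_equal(unname(tr$state[nrow(tr$state), "AbS"]), 67e-9 *
                 (g$V_B + g$V_BB) / g$well_volume_L, tolerance = 1e-3)
})

test_that("ligand-receptor binding matches the two-state closed form", {
  # well-mixed (large D), fixed receptor pool (no synthesis, decay or
  # internalization), ligand in vast excess: C(t) relaxes to
  # R*L/(K_D+L) at rate k_on*L + k_off
  cfg <- default_config("HBEGF")
  cfg$ligands[[1]]$K_D_nM <- 10
  cfg$ligands[[1]]$Q_molecules_cell_min <- 0
  cfg$ligands[[1]]$L0_nM <- 10
  cfg$ligands[[1]]$D_cm2_s <- 1
  cfg$geometry$n_cells <- 100
  cfg$receptor <- list(R0 = 100, k_t_min = 0, k_e_min = 0, q_R_min = 0)
  sys <- build_system(cfg)
  tr <- simulate_system(sys, hours = 0.1)
  L0 <- 10e-9
  rate <- 1e8 * L0 + 1e8 * 10e-9
  C_exp <- 100 * L0 / (10e-9 + L0) * (1 - exp(-rate * tr$time))
  i <- tr$time > 0
  expect_lt(max(abs(tr$state[i, "C.HBEGF"] - C_exp[i]) / C_exp[i]), 1e-4)
})

test_that("mass is conserved and states stay non-negative", {
  for (kd in c(0.5, 50, 5000)) {
    tr <- simulate_system(tiny_system(K_D_nM = kd))
    expect_lt(conservation_residual(tr), 1e-6)
    expect_true(all(tr$state >= -tr$diagnostics$atol))
    # cumulative fluxes never decrease
    expect_true(all(diff(tr$state[, "cumRel.HBEGF"]) >= 0))
    expect_true(all(diff(tr$state[, "cumInt.HBEGF"]) >= -1e-12))
  }
})

test_that("perturbed states break the mass balance detectably", {
  tr <- simulate_system(tiny_system())
  expect_lt(conservation_residual(tr), 1e-6)
  tr$state[, "C.HBEGF"] <- tr$state[, "C.HBEGF"] * 1.01
  tr$state[, "LBB.HBEGF"] <- tr$state[, "LBB.HBEGF"] * 1.01
  tr$state[, "cumInt.HBEGF"] <- tr$state[, "cumInt.HBEGF"] * 1.01
  expect_gt(conservation_residual(tr), 1e-3)
})

test_that("full receptor blockade abolishes capture", {
  sys <- tiny_system()
  sys <- set_parameter(sys, "receptor.blockade_fraction", 1)
  tr <- simulate_system(sys)
  expect_lt(capture_fraction(tr), 1e-6)
})

test_that("capture fraction tends to one for a tight, closed system", {
  # essentially irreversible binding (K_D 1e-6 nM), long horizon: the
  # well is closed, so everything shed is eventually internalized
  sys <- tiny_system(K_D_nM = 1e-6)
  tr <- simulate_system(sys, hours = 240, n_grid = 481)
  expect_gt(capture_fraction(tr), 0.99)
})

test_that("well-mixed limit matches a one-compartment reference", {
  cfg <- default_config("HBEGF")
  cfg$ligands[[1]]$D_cm2_s <- 1 # collapse the boundary layers
  sys <- build_system(cfg)
  tr <- simulate_system(sys, hours = 6)
  n <- nrow(tr$state)
  # compartment concentrations agree within 1%
  LS <- tr$state[n, "LS.HBEGF"]; LBB <- tr$state[n, "LBB.HBEGF"]
  expect_lt(abs(LS - LBB) / LBB, 0.01)
  ref <- single_compartment_reference(sys, hours = 6)
  m <- nrow(ref)
  expect_equal(unname(tr$state[n, "C.HBEGF"]), ref$C[m], tolerance = 1e-4)
  expect_equal(unname(LBB), ref$L[m], tolerance = 1e-4)
  expect_equal(capture_fraction(tr),
               ref$cumInt[m] / ref$cumRel[m], tolerance = 1e-4)
})

test_that("capture depends on the flux k_Q*P, not the protease count", {
  base <- capture_fraction(simulate_system(tiny_system()))
  for (P in c(500, 50000)) {
    cfg <- default_config("HBEGF")
    cfg$protease$P <- P
    cf <- capture_fraction(simulate_system(build_system(cfg)))
    expect_lt(abs(cf - base), 0.01)
  }
})

test_that("free_ligand_fraction complements capture_fraction", {
  for (kd in c(1, 100, 10000)) {
    sys <- tiny_system(K_D_nM = kd)
    ff <- free_ligand_fraction(sys)
    cf <- capture_fraction(simulate_system(sys))
    expect_lt(abs((1 - ff) - cf), 0.05)
  }
  # K_D = 10 uM: nearly everything escapes
  expect_gt(free_ligand_fraction(tiny_system(K_D_nM = 1e4)), 0.6)
  # release rate 0: undefined in both arms
  expect_error(free_ligand_fraction(tiny_system(Q = 0)), "undefined")
})

test_that("trajectory exports tidily", {
  tr <- simulate_system(tiny_system(), hours = 1)
  df <- as.data.frame(tr)
  expect_setequal(unique(df$species), colnames(tr$state))
  expect_equal(nrow(df), length(tr$time) * ncol(tr$state))
  expect_equal(unique(df$units[df$species == "R"]), "molecules/cell")
  expect_equal(unique(df$units[df$species == "LBB.HBEGF"]), "mol/L")
})
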