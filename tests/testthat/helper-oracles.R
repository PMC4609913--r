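# Independent oracles the tests check the implementation against. These
# stay deliberately naive: brute-force enumeration, closed forms, and a
# from-scratch one-compartment ODE.

# Exhaustive non-negative grid search for min ||A x - b||, x >= 0.
# Only usable for <= 2 unknowns at the stated resolution.
brute_nnls <- function(A, b, upper = 2, res = 1e-3) {
  stopifnot(ncol(A) <= 2)
  grid <- seq(0, upper, by = res)
  if (ncol(A) == 1) {
    sse <- vapply(grid, function(x) sum((b - A[, 1] * x)^2), numeric(1))
    return(grid[which.min(sse)])
  }
  best <- c(NA, NA); best_sse <- Inf
  for (x1 in grid) {
    r1 <- b - A[, 1] * x1
    sse <- colSums((outer(A[, 2], grid) - r1)^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) { best_sse <- sse[j]; best <- c(x1, grid[j]) }
  }
  best
}

# Pearson r and two-tailed t-test p from the textbook formulas.
hand_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# From-scratch single-compartment autocrine reference: one well-mixed
# volume, receptor trafficking, release and internalization. States:
# R, C (molecules/cell), L (M), cumRel, cumInt (molecules/cell).
single_compartment_reference <- function(sys, hours, n_grid = 241) {
  lig <- sys$ligands[[1]]
  g <- sys$geometry
  prm <- list(kon = lig$k_on, koff = lig$k_off,
              qR = sys$receptor$q_R, kt = sys$receptor$k_t,
              ke = sys$receptor$k_e,
              Q = lig$Q,
              conv = g$n_cells / (6.02214076e23 * g$well_volume_L))
  rhs <- function(t, y, p) with(as.list(c(y, p)), {
    bind <- kon * L * R
    unbind <- koff * C
    list(c(R = qR - kt * R - bind + unbind,
           C = bind - (koff + ke) * C,
           L = (Q - bind + unbind) * conv,
           cumRel = Q,
           cumInt = ke * C))
  })
  y0 <- c(R = sys$receptor$R0 * (1 - sys$receptor$blockade_fraction),
          C = 0, L = 0, cumRel = 0, cumInt = 0)
  times <- seq(0, hours * 60, length.out = n_grid)
  out <- deSolve::lsoda(y0, times, rhs, prm, rtol = 1e-10, atol = 1e-14)
  as.data.frame(out)
}

# Fast small system for tests that only need a valid simulable model.
tiny_system <- function(K_D_nM = 1, Q = 10, ...) {
  cfg <- default_config("HBEGF")
  cfg$ligands[[1]]$K_D_nM <- K_D_nM
  cfg$ligands[[1]]$Q_molecules_cell_min <- Q
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  build_system(cfg)
}
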