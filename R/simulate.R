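## Three-compartment ODE of autocrine shedding, diffusion and capture.
##
## State layout (built by .state_template):
##   R                      free surface receptors        molecules/cell
##   C.<lig>                ligand-receptor complexes     molecules/cell
##   LS/LB/LBB.<lig>        free ligand per compartment   mol/L
##   cumRel.<lig>           cumulative shed ligand        molecules/cell
##   cumInt.<lig>           cumulative internalized       molecules/cell
##   AbS/AbB/AbBB           free decoy antibody           mol/L
##   AbLS/AbLB/AbLBB.<lig>  antibody-ligand complex       mol/L
##   IS/IB/IBB              free inhibitor                mol/L
##   PI.<lig>               inhibitor-protease complex    molecules/cell
##
## Shedding enters V_S as a per-cell flux k_Q * P_free; inter-compartment
## diffusion is Delta_ij * (conc_i - conc_j) with Delta_ij = D * A / delta_ij.

.state_template <- function(sys) {
  lig <- names(sys$ligands)
  nm <- c("R",
          paste0("C.", lig),
          paste0("LS.", lig), paste0("LB.", lig), paste0("LBB.", lig),
          paste0("cumRel.", lig), paste0("cumInt.", lig))
  if (!is.null(sys$decoy))
    nm <- c(nm, "AbS", "AbB", "AbBB",
            paste0("AbLS.", lig), paste0("AbLB.", lig), paste0("AbLBB.", lig))
  if (!is.null(sys$inhibitor))
    nm <- c(nm, "IS", "IB", "IBB", paste0("PI.", sys$inhibitor$targets))
  nm
}

.initial_state <- function(sys) {
  nm <- .state_template(sys)
  y <- setNames(numeric(length(nm)), nm)
  y["R"] <- sys$receptor$R0 * (1 - sys$receptor$blockade_fraction)
  for (nm in names(sys$ligands)) { # optional pre-loaded (exogenous) ligand
    L0 <- sys$ligands[[nm]]$L0
    if (L0 > 0) y[paste0(c("LS.", "LB.", "LBB."), nm)] <- L0
  }
  if (!is.null(sys$decoy)) { # bulk initialization: V_B and V_BB only
    y["AbB"] <- sys$decoy$dose
    y["AbBB"] <- sys$decoy$dose
  }
  if (!is.null(sys$inhibitor)) {
    y["IB"] <- sys$inhibitor$dose
    y["IBB"] <- sys$inhibitor$dose
  }
  y
}

.ode_rhs <- function(t, y, pp) {
  with(pp, {
    dy <- numeric(length(y))
    R <- y[i_R]
    dR <- q_R_eff - k_t * R

    if (has_inh) {
      IS <- y[i_IS]; IB <- y[i_IB]; IBB <- y[i_IBB]
      dIS <- 0; dIB <- 0; dIBB <- 0
    }

    for (j in seq_len(n_lig)) {
      C <- y[i_C[j]]
      LS <- y[i_LS[j]]; LB <- y[i_LB[j]]; LBB <- y[i_LBB[j]]

      Pfree <- P[j]
      if (has_inh && inh_mask[j]) {
        PI <- y[i_PI[j]]
        Pfree <- P[j] - PI
        ibind <- ki_on * IS * Pfree - ki_off * PI     # molecules/cell/min
        dy[i_PI[j]] <- ibind
        dIS <- dIS - ibind * cells_per_VS
      }
      rel <- k_Q[j] * Pfree                           # molecules/cell/min
      bind <- k_on[j] * LS * R                        # molecules/cell/min
      unbind <- k_off[j] * C

      dR <- dR - bind + unbind
      dy[i_C[j]] <- bind - (k_off[j] + k_e) * C
      dy[i_cumRel[j]] <- rel
      dy[i_cumInt[j]] <- k_e * C

      fSB <- dSB[j] * (LS - LB)                       # mol/min
      fBBB <- dBBB[j] * (LB - LBB)
      dLS <- (rel - bind + unbind) * cells_per_VS - fSB / V_S
      dLB <- fSB / V_B - fBBB / V_B
      dLBB <- fBBB / V_BB

      if (has_ab) {
        AbS <- y[i_AbS]; AbB <- y[i_AbB]; AbBB <- y[i_AbBB]
        aS <- ka_on * AbS * LS - ka_off * y[i_AbLS[j]]   # M/min
        aB <- ka_on * AbB * LB - ka_off * y[i_AbLB[j]]
        aBB <- ka_on * AbBB * LBB - ka_off * y[i_AbLBB[j]]
        dLS <- dLS - aS; dLB <- dLB - aB; dLBB <- dLBB - aBB
        gSB <- abSB * (y[i_AbLS[j]] - y[i_AbLB[j]])
        gBBB <- abBBB * (y[i_AbLB[j]] - y[i_AbLBB[j]])
        dy[i_AbLS[j]] <- aS - gSB / V_S
        dy[i_AbLB[j]] <- aB + gSB / V_B - gBBB / V_B
        dy[i_AbLBB[j]] <- aBB + gBBB / V_BB
        dy[i_AbS] <- dy[i_AbS] - aS
        dy[i_AbB] <- dy[i_AbB] - aB
        dy[i_AbBB] <- dy[i_AbBB] - aBB
      }

      dy[i_LS[j]] <- dLS; dy[i_LB[j]] <- dLB; dy[i_LBB[j]] <- dLBB
    }

    if (has_ab) { # free antibody diffusion
      hSB <- abSB * (y[i_AbS] - y[i_AbB])
      hBBB <- abBBB * (y[i_AbB] - y[i_AbBB])
      dy[i_AbS] <- dy[i_AbS] - hSB / V_S
      dy[i_AbB] <- dy[i_AbB] + hSB / V_B - hBBB / V_B
      dy[i_AbBB] <- dy[i_AbBB] + hBBB / V_BB
    }
    if (has_inh) {
      hSB <- inSB * (IS - IB)
      hBBB <- inBBB * (IB - IBB)
      dy[i_IS] <- dIS - hSB / V_S
      dy[i_IB] <- dIB + hSB / V_B - hBBB / V_B
      dy[i_IBB] <- dIBB + hBBB / V_BB
    }

    dy[i_R] <- dR
    list(dy)
  })
}

.pack_params <- function(sys) {
  g <- sys$geometry
  lig <- sys$ligands
  nm <- .state_template(sys)
  idx <- function(x) match(x, nm)
  lnames <- names(lig)
  tr <- lapply(lig, function(l) .transport(g, l$D_cm2_s))

  pp <- list(
    n_lig = length(lig),
    V_S = g$V_S, V_B = g$V_B, V_BB = g$V_BB,
    cells_per_VS = g$n_cells / (.N_A * g$V_S),
    q_R_eff = sys$receptor$q_R * (1 - sys$receptor$blockade_fraction),
    k_t = sys$receptor$k_t, k_e = sys$receptor$k_e,
    k_on = vapply(lig, `[[`, numeric(1), "k_on"),
    k_off = vapply(lig, `[[`, numeric(1), "k_off"),
    k_Q = vapply(sys$protease, `[[`, numeric(1), "k_Q"),
    P = vapply(sys$protease, `[[`, numeric(1), "P"),
    dSB = vapply(tr, `[[`, numeric(1), "SB"),
    dBBB = vapply(tr, `[[`, numeric(1), "BBB"),
    i_R = idx("R"),
    i_C = idx(paste0("C.", lnames)),
    i_LS = idx(paste0("LS.", lnames)),
    i_LB = idx(paste0("LB.", lnames)),
    i_LBB = idx(paste0("LBB.", lnames)),
    i_cumRel = idx(paste0("cumRel.", lnames)),
    i_cumInt = idx(paste0("cumInt.", lnames)),
    has_ab = !is.null(sys$decoy),
    has_inh = !is.null(sys$inhibitor)
  )
  if (pp$has_ab) {
    abtr <- .transport(g, sys$decoy$D_cm2_s)
    pp$ka_on <- sys$decoy$k_on; pp$ka_off <- sys$decoy$k_off
    pp$abSB <- abtr$SB; pp$abBBB <- abtr$BBB
    pp$i_AbS <- idx("AbS"); pp$i_AbB <- idx("AbB"); pp$i_AbBB <- idx("AbBB")
    pp$i_AbLS <- idx(paste0("AbLS.", lnames))
    pp$i_AbLB <- idx(paste0("AbLB.", lnames))
    pp$i_AbLBB <- idx(paste0("AbLBB.", lnames))
  }
  if (pp$has_inh) {
    intr <- .transport(g, sys$inhibitor$D_cm2_s)
    pp$ki_on <- sys$inhibitor$k_on; pp$ki_off <- sys$inhibitor$k_off
    pp$inSB <- intr$SB; pp$inBBB <- intr$BBB
    pp$inh_mask <- lnames %in% sys$inhibitor$targets
    pp$i_IS <- idx("IS"); pp$i_IB <- idx("IB"); pp$i_IBB <- idx("IBB")
    pp$i_PI <- rep(NA_integer_, pp$n_lig)
    pp$i_PI[pp$inh_mask] <- idx(paste0("PI.", lnames[pp$inh_mask]))
  }
  pp
}

#' Simulate an autocrine system
#'
#' Integrates the three-compartment model over `hours` with a stiff
#' solver (lsoda, rtol 1e-8, atol 1e-12) on a fixed output grid. Surface
#' species (receptors, complexes, inhibitor-protease complexes, cumulative
#' release/internalization) are tracked in molecules/cell; soluble species
#' in mol/L per compartment.
#'
#' @param sys validated `autocrine_system`.
#' @param hours simulation span (default 24 h, the span all summary
#'   readouts are defined over).
#' @param n_grid number of output time points (>= 200 by contract).
#' @param rtol,atol solver tolerances.
#' @return An object of class `autocrine_trajectory`: list with `time`
#'   (minutes), `state` (matrix time x species), `sys`, and `diagnostics`.
#' @examples
#' tr <- simulate_system(build_system(default_config("HBEGF")), hours = 1)
#' capture_fraction(tr, "HBEGF")
#' @export
simulate_system <- function(sys, hours = 24, n_grid = 241,
                            rtol = 1e-8, atol = 1e-12) {
  validate_system(sys)
  if (!is.numeric(hours) || hours <= 0) stop("hours must be > 0")
  n_grid <- max(as.integer(n_grid), 200L)
  times <- seq(0, hours * 60, length.out = n_grid)
  y0 <- .initial_state(sys)
  pp <- .pack_params(sys)

  out <- deSolve::lsoda(y = y0, times = times, func = .ode_rhs, parms = pp,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  istate <- attr(out, "istate")[1]
  if (istate < 0 || nrow(out) < length(times))
    stop("ODE integration failed (istate = ", istate,
         "); rtol = ", rtol, ", atol = ", atol, call. = FALSE)
  state <- out[, -1, drop = FALSE]
  if (any(!is.finite(state)))
    stop("non-finite state encountered during integration", call. = FALSE)

  structure(list(time = times, state = state, sys = sys,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    istate = istate, success = TRUE)),
            class = "autocrine_trajectory")
}

#' @export
print.autocrine_trajectory <- function(x, ...) {
  cat(sprintf("Autocrine trajectory: %d time points over %.3g h, %d species\n",
              length(x$time), max(x$time) / 60, ncol(x$state)))
  for (nm in names(x$sys$ligands)) {
    rel <- x$state[nrow(x$state), paste0("cumRel.", nm)]
    cf <- if (rel > 0)
      x$state[nrow(x$state), paste0("cumInt.", nm)] / rel else NA_real_
    cat(sprintf("  %s: released %.3g molecules/cell, capture fraction %.3f\n",
                nm, rel, cf))
  }
  invisible(x)
}

## Per-ligand molecule bookkeeping (molecules/cell) at every output time.
.ligand_balance <- function(traj, ligand) {
  sys <- traj$sys
  g <- sys$geometry
  st <- traj$state
  per_cell <- .N_A / g$n_cells
  free <- (st[, paste0("LS.", ligand)] * g$V_S +
           st[, paste0("LB.", ligand)] * g$V_B +
           st[, paste0("LBB.", ligand)] * g$V_BB) * per_cell
  ab <- if (!is.null(sys$decoy))
    (st[, paste0("AbLS.", ligand)] * g$V_S +
     st[, paste0("AbLB.", ligand)] * g$V_B +
     st[, paste0("AbLBB.", ligand)] * g$V_BB) * per_cell
  else rep(0, nrow(st))
  L0 <- sys$ligands[[ligand]]$L0
  initial <- L0 * (g$V_S + g$V_B + g$V_BB) * per_cell
  list(released = st[, paste0("cumRel.", ligand)],
       initial = initial,
       free = free, antibody = ab,
       bound = st[, paste0("C.", ligand)],
       internalized = st[, paste0("cumInt.", ligand)])
}

#' Cumulative capture fraction of a released ligand
#'
#' Fraction of all ligand proteolytically shed over the trajectory that
#' ended up internalized through receptor complexes:
#' `cumInt / cumRel` at the final time.
#'
#' @param traj `autocrine_trajectory`.
#' @param ligand ligand name (default: the first ligand).
#' @return scalar in \[0, 1\] (within solver tolerance).
#' @export
capture_fraction <- function(traj, ligand = names(traj$sys$ligands)[1]) {
  stopifnot(inherits(traj, "autocrine_trajectory"))
  if (!ligand %in% names(traj$sys$ligands))
    stop("unknown ligand '", ligand, "'", call. = FALSE)
  n <- nrow(traj$state)
  rel <- traj$state[n, paste0("cumRel.", ligand)]
  if (rel <= 0)
    stop("no ligand was released; capture fraction is undefined",
         call. = FALSE)
  unname(traj$state[n, paste0("cumInt.", ligand)] / rel)
}

#' Mass-balance residual of a trajectory
#'
#' For each ligand, everything shed must be somewhere: free in one of the
#' three compartments, antibody-complexed, receptor-bound, or already
#' internalized. Returns the maximum over time and ligands of
#' `|released - (free + antibody + bound + internalized)| /
#' max(released, 1 molecule/cell)`.
#'
#' @param traj `autocrine_trajectory`.
#' @return dimensionless residual (<= 1e-6 for converged runs).
#' @export
conservation_residual <- function(traj) {
  stopifnot(inherits(traj, "autocrine_trajectory"))
  res <- 0
  for (nm in names(traj$sys$ligands)) {
    b <- .ligand_balance(traj, nm)
    err <- abs(b$released + b$initial -
               (b$free + b$antibody + b$bound + b$internalized)) /
      pmax(b$released + b$initial, 1)
    res <- max(res, err)
  }
  res
}

#' Bulk free-ligand fraction by paired blockade simulation
#'
#' Emulates the receptor-blockade experiment: simulates the system twice,
#' once with complete receptor blockade and once without, and returns the
#' ratio of bulk free-ligand accumulation (all compartments) at the final
#' time, unblocked over blocked. This is the experimentally accessible
#' complement of capture: with capture off, all shed ligand accumulates;
#' with capture on, only the uncaptured portion does. `1 - free fraction`
#' tracks [capture_fraction()] to within a few percent; the residual is
#' ligand still in transit or receptor-bound (not yet internalized) at the
#' final time.
#'
#' @param sys `autocrine_system`.
#' @param ligand ligand name.
#' @param hours simulation span.
#' @return fraction in \[0, 1\].
#' @export
free_ligand_fraction <- function(sys, ligand = names(sys$ligands)[1],
                                 hours = 24) {
  sys_open <- set_parameter(sys, "receptor.blockade_fraction", 0)
  sys_blk <- set_parameter(sys, "receptor.blockade_fraction", 1)
  acc <- function(s) {
    tr <- simulate_system(s, hours = hours)
    b <- .ligand_balance(tr, ligand)
    n <- length(b$free)
    b$free[n] + b$antibody[n]
  }
  blocked <- acc(sys_blk)
  if (blocked <= 0)
    stop("no ligand accumulated under receptor blockade; ",
         "free-ligand fraction is undefined", call. = FALSE)
  min(1, acc(sys_open) / blocked)
}

#' Total ligand-receptor complexes at the end of a trajectory
#'
#' The model's "total receptor signaling" readout: ligand-receptor
#' complexes summed over ligands at the final simulated time
#' (molecules/cell).
#'
#' @param traj `autocrine_trajectory`.
#' @param ligands subset of ligand names (default all).
#' @return complexes per cell.
#' @export
total_complexes <- function(traj, ligands = names(traj$sys$ligands)) {
  stopifnot(inherits(traj, "autocrine_trajectory"))
  n <- nrow(traj$state)
  sum(traj$state[n, paste0("C.", ligands)])
}

#' Export a trajectory as a tidy data frame
#'
#' @param x `autocrine_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns time_min, species, value, units.
#' @export
as.data.frame.autocrine_trajectory <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  molec <- grepl("^(R$|C\\.|cumRel\\.|cumInt\\.|PI\\.)",
                 colnames(x$state))
  data.frame(
    time_min = rep(x$time, ncol(x$state)),
    species = rep(colnames(x$state), each = length(x$time)),
    value = as.vector(x$state),
    units = rep(ifelse(molec, "molecules/cell", "mol/L"),
                each = length(x$time)),
    stringsAsFactors = FALSE)
}
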