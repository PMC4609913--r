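## Constants used throughout: concentrations in mol/L, volumes in L,
## time in minutes, diffusivities supplied in cm^2/s, surface species in
## molecules/cell.

#' Avogadro constant (molecules per mole)
#' @keywords internal
.N_A <- 6.02214076e23

## cm^3 -> L
.CM3_TO_L <- 1e-3

#' Default configuration for a 12Z-like autocrine system
#'
#' Returns the complete default parameterization of the model: the
#' geometry of a 100 uL well of a 96-well plate with a 2 um cell-surface
#' boundary layer and a 50 um monolayer boundary layer, an EGFR-like
#' receptor, and two ligands patterned on HB-EGF (high affinity, ~1 nM)
#' and amphiregulin (low affinity, ~100 nM). Every entry can be
#' overridden through [build_system()].
#'
#' Release rates are a lumped flux k_Q * P in molecules/cell/min at the
#' scale measured for endometriotic 12Z cells by receptor-blocked
#' supernatant accumulation; protease abundance P defaults to 5000
#' copies/cell with k_Q derived so that k_Q * P equals the stated flux.
#'
#' @param ligands character vector naming which default ligands to
#'   include: any subset of `"HBEGF"` and `"AREG"`.
#' @return A nested list with sections `geometry`, `ligands`, `receptor`,
#'   `protease` suitable for [build_system()].
#' @export
default_config <- function(ligands = c("HBEGF", "AREG")) {
  ligands <- match.arg(ligands, several.ok = TRUE)
  lig_defaults <- list(
    HBEGF = list(name = "HBEGF", K_D_nM = 1, k_on_M_min = 1e8,
                 D_cm2_s = 1e-6, Q_molecules_cell_min = 10, mw_kDa = 10),
    AREG  = list(name = "AREG", K_D_nM = 100, k_on_M_min = 1e8,
                 D_cm2_s = 1e-6, Q_molecules_cell_min = 70, mw_kDa = 11)
  )
  list(
    geometry = list(
      well_volume_uL = 100,
      cell_layer_um = 2,
      boundary_layer_um = 50,
      well_area_cm2 = 0.32,
      n_cells = 3e4
    ),
    ligands = unname(lig_defaults[ligands]),
    receptor = list(
      R0 = 2e5,
      k_t_min = 0.03,
      k_e_min = 0.15,
      blockade_fraction = 0
    ),
    protease = list(P = 5000)
  )
}

#' Default decoy-antibody specification
#'
#' Sub-nanomolar-affinity (K_D = 0.1 nM) monovalent ligand binder, IgG-like
#' size (150 kDa, D = 4e-7 cm^2/s), initialized in the bulk compartments.
#'
#' @param dose_nM bulk concentration at t = 0 (nM).
#' @return list suitable for the `decoy` section of [build_system()].
#' @export
default_decoy <- function(dose_nM = 0) {
  list(K_D_nM = 0.1, k_on_M_min = 1e8, D_cm2_s = 4e-7,
       dose_nM = dose_nM, mw_kDa = 150)
}

#' Default protease-inhibitor specification
#'
#' Prodomain-like inhibitor of the sheddase: reversible 1:1 binding to the
#' free enzyme with K_i defaulting to the 430 nM scale measured for the
#' ADAM12 prodomain, off-rate derived as K_i * k_on.
#'
#' @param dose_nM bulk concentration at t = 0 (nM).
#' @param K_i_nM inhibition constant (nM).
#' @param targets character vector of ligand names whose sheddase the
#'   inhibitor binds; `NULL` (default) targets every ligand's protease.
#' @return list suitable for the `inhibitor` section of [build_system()].
#' @export
default_inhibitor <- function(dose_nM = 0, K_i_nM = 430, targets = NULL) {
  list(K_i_nM = K_i_nM, k_on_M_min = 1e6, D_cm2_s = 1e-6,
       dose_nM = dose_nM, targets = targets)
}

.assert_scalar <- function(x, field, nonneg = TRUE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("field '", field, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("field '", field, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("field '", field, "' must be >= 0", call. = FALSE)
  x
}

.check_keys <- function(x, allowed, section) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) in ", section, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
}

## Resolve (K_D, k_on, k_off): any two determine the third; all three must
## be mutually consistent if over-specified.
.resolve_affinity <- function(K_D = NULL, k_on = NULL, k_off = NULL, what) {
  n_given <- sum(!vapply(list(K_D, k_on, k_off), is.null, logical(1)))
  if (n_given < 2)
    stop(what, ": supply at least two of K_D, k_on, k_off", call. = FALSE)
  if (is.null(k_off)) k_off <- K_D * k_on
  if (is.null(k_on)) k_on <- k_off / K_D
  if (is.null(K_D)) K_D <- k_off / k_on
  if (abs(K_D * k_on - k_off) > 1e-9 * max(k_off, .Machine$double.xmin))
    stop(what, ": K_D, k_on, k_off are mutually inconsistent ",
         "(K_D * k_on != k_off)", call. = FALSE)
  list(K_D = K_D, k_on = k_on, k_off = k_off)
}

.build_geometry <- function(g) {
  .check_keys(g, c("well_volume_uL", "cell_layer_um", "boundary_layer_um",
                   "well_area_cm2", "n_cells"), "geometry")
  well_volume_L <- .assert_scalar(g$well_volume_uL, "well_volume_uL",
                                  positive = TRUE) * 1e-6
  d_S_cm <- .assert_scalar(g$cell_layer_um, "cell_layer_um",
                           positive = TRUE) * 1e-4
  d_B_cm <- .assert_scalar(g$boundary_layer_um, "boundary_layer_um",
                           positive = TRUE) * 1e-4
  A_cm2 <- .assert_scalar(g$well_area_cm2, "well_area_cm2", positive = TRUE)
  n_cells <- .assert_scalar(g$n_cells, "n_cells", positive = TRUE)

  V_S <- A_cm2 * d_S_cm * .CM3_TO_L
  V_B <- A_cm2 * d_B_cm * .CM3_TO_L
  V_BB <- well_volume_L - V_S - V_B
  if (V_BB <= 0)
    stop("boundary layers exceed the well volume", call. = FALSE)
  d_BB_cm <- V_BB / .CM3_TO_L / A_cm2
  list(well_volume_L = well_volume_L, well_area_cm2 = A_cm2,
       n_cells = n_cells,
       d_S_cm = d_S_cm, d_B_cm = d_B_cm, d_BB_cm = d_BB_cm,
       V_S = V_S, V_B = V_B, V_BB = V_BB)
}

## Transport coefficients (L/min) for a species of diffusivity D (cm^2/s):
## Delta_ij = D * A / delta_ij, delta_ij the mean of the adjoining layer
## thicknesses. Linear in D by construction.
.transport <- function(geom, D_cm2_s) {
  D <- D_cm2_s * 60 # cm^2/min
  delta_SB <- (geom$d_S_cm + geom$d_B_cm) / 2
  delta_BBB <- (geom$d_B_cm + geom$d_BB_cm) / 2
  list(SB = D * geom$well_area_cm2 / delta_SB * .CM3_TO_L,
       BBB = D * geom$well_area_cm2 / delta_BBB * .CM3_TO_L)
}

.build_ligand <- function(l, i) {
  sec <- paste0("ligands[[", i, "]]")
  .check_keys(l, c("name", "K_D_nM", "k_on_M_min", "k_off_min", "D_cm2_s",
                   "Q_molecules_cell_min", "mw_kDa", "L0_nM"), sec)
  name <- if (is.null(l$name)) paste0("ligand", i) else as.character(l$name)
  aff <- .resolve_affinity(
    K_D = if (is.null(l$K_D_nM)) NULL else
      .assert_scalar(l$K_D_nM, paste0(sec, "$K_D_nM"), positive = TRUE) * 1e-9,
    k_on = if (is.null(l$k_on_M_min)) NULL else
      .assert_scalar(l$k_on_M_min, paste0(sec, "$k_on_M_min"), positive = TRUE),
    k_off = if (is.null(l$k_off_min)) NULL else
      .assert_scalar(l$k_off_min, paste0(sec, "$k_off_min")),
    what = name)
  list(name = name,
       K_D = aff$K_D, k_on = aff$k_on, k_off = aff$k_off,
       D_cm2_s = .assert_scalar(l$D_cm2_s %||% 1e-6,
                                paste0(sec, "$D_cm2_s"), positive = TRUE),
       Q = .assert_scalar(l$Q_molecules_cell_min %||% 0,
                          paste0(sec, "$Q_molecules_cell_min")),
       L0 = .assert_scalar(l$L0_nM %||% 0, paste0(sec, "$L0_nM")) * 1e-9,
       mw_kDa = .assert_scalar(l$mw_kDa %||% 10, paste0(sec, "$mw_kDa"),
                               positive = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble and validate an autocrine signaling system
#'
#' Builds the complete, validated parameterization of the
#' three-compartment model from a nested configuration list (see
#' [default_config()] for the shape and the shipped defaults). All derived
#' quantities are populated here: compartment volumes `V_S` (2 um slab over
#' the monolayer), `V_B` (50 um boundary layer) and `V_BB` (remaining bulk);
#' per-species diffusive transport coefficients `Delta = D * A / delta`;
#' receptor synthesis `q_R = R0 * k_t` (resting steady state `R_ss = R0`);
#' and the per-protease shedding rate `k_Q = Q / P`.
#'
#' Unknown keys in any section are rejected, as are negative rates and
#' volumes, and over-specified inconsistent affinity triples
#' (`K_D * k_on != k_off`).
#'
#' @param config nested list with sections `geometry`, `ligands`,
#'   `receptor`, `protease`, and optionally `decoy` and `inhibitor`; or a
#'   path to a YAML/JSON file with the same structure.
#' @return An object of class `autocrine_system`.
#' @examples
#' sys <- build_system(default_config())
#' sys
#' @export
build_system <- function(config = default_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  .check_keys(config, c("geometry", "ligands", "receptor", "protease",
                        "decoy", "inhibitor"), "config")
  if (is.null(config$geometry) || is.null(config$ligands) ||
      is.null(config$receptor))
    stop("config must supply geometry, ligands and receptor sections",
         call. = FALSE)

  geom <- .build_geometry(config$geometry)
  ligands <- lapply(seq_along(config$ligands), function(i)
    .build_ligand(config$ligands[[i]], i))
  names(ligands) <- vapply(ligands, `[[`, character(1), "name")
  if (anyDuplicated(names(ligands)))
    stop("duplicate ligand names", call. = FALSE)

  r <- config$receptor
  .check_keys(r, c("R0", "k_t_min", "k_e_min", "blockade_fraction", "q_R_min"),
              "receptor")
  R0 <- .assert_scalar(r$R0, "receptor$R0")
  k_t <- .assert_scalar(r$k_t_min, "receptor$k_t_min")
  blockade <- .assert_scalar(r$blockade_fraction %||% 0,
                             "receptor$blockade_fraction")
  if (blockade < 0 || blockade > 1)
    stop("receptor$blockade_fraction must lie in [0, 1]", call. = FALSE)
  receptor <- list(
    R0 = R0, k_t = k_t,
    k_e = .assert_scalar(r$k_e_min, "receptor$k_e_min"),
    q_R = .assert_scalar(r$q_R_min %||% (R0 * k_t), "receptor$q_R_min"),
    blockade_fraction = blockade)

  p <- config$protease %||% list(P = 5000)
  .check_keys(p, c("P"), "protease")
  P <- .assert_scalar(p$P %||% 5000, "protease$P", positive = TRUE)
  protease <- lapply(ligands, function(l) list(P = P, k_Q = l$Q / P))

  decoy <- NULL
  if (!is.null(config$decoy)) {
    d <- config$decoy
    .check_keys(d, c("K_D_nM", "k_on_M_min", "k_off_min", "D_cm2_s",
                     "dose_nM", "mw_kDa"), "decoy")
    aff <- .resolve_affinity(
      K_D = if (is.null(d$K_D_nM)) NULL else
        .assert_scalar(d$K_D_nM, "decoy$K_D_nM", positive = TRUE) * 1e-9,
      k_on = if (is.null(d$k_on_M_min)) NULL else
        .assert_scalar(d$k_on_M_min, "decoy$k_on_M_min", positive = TRUE),
      k_off = if (is.null(d$k_off_min)) NULL else
        .assert_scalar(d$k_off_min, "decoy$k_off_min"),
      what = "decoy")
    decoy <- list(K_D = aff$K_D, k_on = aff$k_on, k_off = aff$k_off,
                  D_cm2_s = .assert_scalar(d$D_cm2_s %||% 4e-7,
                                           "decoy$D_cm2_s", positive = TRUE),
                  dose = .assert_scalar(d$dose_nM %||% 0,
                                        "decoy$dose_nM") * 1e-9,
                  mw_kDa = .assert_scalar(d$mw_kDa %||% 150, "decoy$mw_kDa",
                                          positive = TRUE))
  }

  inhibitor <- NULL
  if (!is.null(config$inhibitor)) {
    h <- config$inhibitor
    .check_keys(h, c("K_i_nM", "k_on_M_min", "k_off_min", "D_cm2_s",
                     "dose_nM", "targets"), "inhibitor")
    aff <- .resolve_affinity(
      K_D = if (is.null(h$K_i_nM)) NULL else
        .assert_scalar(h$K_i_nM, "inhibitor$K_i_nM", positive = TRUE) * 1e-9,
      k_on = if (is.null(h$k_on_M_min)) NULL else
        .assert_scalar(h$k_on_M_min, "inhibitor$k_on_M_min", positive = TRUE),
      k_off = if (is.null(h$k_off_min)) NULL else
        .assert_scalar(h$k_off_min, "inhibitor$k_off_min"),
      what = "inhibitor")
    targets <- h$targets %||% names(ligands)
    bad <- setdiff(targets, names(ligands))
    if (length(bad))
      stop("inhibitor targets unknown ligand(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    inhibitor <- list(K_i = aff$K_D, k_on = aff$k_on, k_off = aff$k_off,
                      D_cm2_s = .assert_scalar(h$D_cm2_s %||% 1e-6,
                                               "inhibitor$D_cm2_s",
                                               positive = TRUE),
                      dose = .assert_scalar(h$dose_nM %||% 0,
                                            "inhibitor$dose_nM") * 1e-9,
                      targets = targets)
  }

  sys <- structure(list(geometry = geom, ligands = ligands,
                        receptor = receptor, protease = protease,
                        decoy = decoy, inhibitor = inhibitor),
                   class = "autocrine_system")
  validate_system(sys)
  sys
}

#' Validate an autocrine system's internal consistency
#'
#' Checks the geometric closure (V_S + V_B + V_BB equals the well volume
#' to 1e-12 relative), positivity of volumes and cell number, affinity
#' consistency for every binding pair, and bounds on the receptor blockade
#' fraction.
#'
#' @param sys an `autocrine_system`.
#' @return `sys`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_system <- function(sys) {
  stopifnot(inherits(sys, "autocrine_system"))
  g <- sys$geometry
  if (abs(g$V_S + g$V_B + g$V_BB - g$well_volume_L) >
      1e-12 * g$well_volume_L)
    stop("compartment volumes do not sum to the well volume", call. = FALSE)
  if (any(c(g$V_S, g$V_B, g$V_BB, g$n_cells) <= 0))
    stop("volumes and n_cells must be positive", call. = FALSE)
  for (l in sys$ligands)
    if (abs(l$K_D * l$k_on - l$k_off) > 1e-9 * max(l$k_off, 1e-300))
      stop("ligand ", l$name, ": K_D * k_on != k_off", call. = FALSE)
  bf <- sys$receptor$blockade_fraction
  if (bf < 0 || bf > 1) stop("blockade_fraction outside [0, 1]",
                             call. = FALSE)
  invisible(sys)
}

#' @export
print.autocrine_system <- function(x, ...) {
  g <- x$geometry
  cat("Autocrine signaling system\n")
  cat(sprintf("  well: %.0f uL over %.2f cm2, %g cells\n",
              g$well_volume_L * 1e6, g$well_area_cm2, g$n_cells))
  cat(sprintf("  compartments (uL): V_S %.3g | V_B %.3g | V_BB %.4g\n",
              g$V_S * 1e6, g$V_B * 1e6, g$V_BB * 1e6))
  cat(sprintf("  receptor: R0 %.3g/cell, k_t %.3g/min, k_e %.3g/min, blockade %.0f%%\n",
              x$receptor$R0, x$receptor$k_t, x$receptor$k_e,
              100 * x$receptor$blockade_fraction))
  for (l in x$ligands)
    cat(sprintf("  ligand %s: K_D %.3g nM, Q %.3g molecules/cell/min, D %.1e cm2/s\n",
                l$name, l$K_D * 1e9, l$Q, l$D_cm2_s))
  if (!is.null(x$decoy))
    cat(sprintf("  decoy: K_D %.3g nM, dose %.3g nM\n",
                x$decoy$K_D * 1e9, x$decoy$dose * 1e9))
  if (!is.null(x$inhibitor))
    cat(sprintf("  inhibitor: K_i %.3g nM, dose %.3g nM (targets: %s)\n",
                x$inhibitor$K_i * 1e9, x$inhibitor$dose * 1e9,
                paste(x$inhibitor$targets, collapse = ", ")))
  invisible(x)
}

#' Modify fields of an existing system configuration
#'
#' Convenience for sweeps: returns a copy of the system with one scalar
#' field replaced, re-deriving all dependent quantities. Paths address the
#' nested structure, e.g. `"ligands.HBEGF.K_D"` (in molar),
#' `"ligands.AREG.Q"`, `"receptor.blockade_fraction"`, `"decoy.dose"`,
#' `"inhibitor.dose"`, `"geometry.n_cells"`.
#'
#' @param sys an `autocrine_system`.
#' @param path dot-separated field path.
#' @param value new scalar value (base units: M, L, min, cm^2/s).
#' @return modified, revalidated `autocrine_system`.
#' @export
set_parameter <- function(sys, path, value) {
  stopifnot(inherits(sys, "autocrine_system"))
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  valid_leaves <- c("K_D", "k_on", "k_off", "D_cm2_s", "Q", "mw_kDa", "L0",
                    "R0", "k_t", "k_e", "q_R", "blockade_fraction",
                    "P", "k_Q", "dose", "K_i", "n_cells",
                    "well_volume_L", "well_area_cm2")
  err_paths <- function() stop(
    "cannot resolve parameter path '", path, "'; paths are dot-separated, ",
    "e.g. ligands.<name>.K_D, receptor.k_e, decoy.dose, inhibitor.K_i, ",
    "geometry.n_cells", call. = FALSE)

  if (length(parts) < 2L) err_paths()
  leaf <- parts[length(parts)]
  if (!leaf %in% valid_leaves) err_paths()

  x <- unclass(sys)
  ref <- x
  for (p in parts[-length(parts)]) {
    if (is.null(ref[[p]])) err_paths()
    ref <- ref[[p]]
  }
  if (!leaf %in% names(ref)) err_paths()
  x[[parts]] <- value

  ## re-derive couplings
  if (parts[1] == "ligands") {
    lig <- x$ligands[[parts[2]]]
    if (leaf == "K_D") lig$k_off <- lig$K_D * lig$k_on
    if (leaf == "k_on") lig$k_off <- lig$K_D * lig$k_on
    if (leaf == "k_off") lig$K_D <- lig$k_off / lig$k_on
    if (leaf == "Q") x$protease[[parts[2]]]$k_Q <- lig$Q / x$protease[[parts[2]]]$P
    x$ligands[[parts[2]]] <- lig
  }
  if (parts[1] == "decoy" && leaf %in% c("K_D", "k_on"))
    x$decoy$k_off <- x$decoy$K_D * x$decoy$k_on
  if (parts[1] == "inhibitor" && leaf %in% c("K_i", "k_on"))
    x$inhibitor$k_off <- x$inhibitor$K_i * x$inhibitor$k_on
  if (parts[1] == "protease" || leaf == "P") {
    for (nm in names(x$protease))
      x$protease[[nm]]$k_Q <- x$ligands[[nm]]$Q / x$protease[[nm]]$P
  }
  if (parts[1] == "geometry") {
    g <- x$geometry
    A <- g$well_area_cm2
    g$V_S <- A * g$d_S_cm * .CM3_TO_L
    g$V_B <- A * g$d_B_cm * .CM3_TO_L
    g$V_BB <- g$well_volume_L - g$V_S - g$V_B
    g$d_BB_cm <- g$V_BB / .CM3_TO_L / A
    x$geometry <- g
  }
  if (parts[1] == "receptor" && leaf %in% c("R0", "k_t"))
    x$receptor$q_R <- x$receptor$R0 * x$receptor$k_t

  out <- structure(x, class = "autocrine_system")
  validate_system(out)
  out
}
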