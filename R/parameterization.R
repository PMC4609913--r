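#' Construct a supernatant immunoassay measurement
#'
#' One well's worth of 24 h supernatant accumulation data: analyte
#' concentration, the matching metalloproteinase-inhibitor (background)
#' control, culture volume, viable-cell count used for normalization, and
#' whether receptor capture was blocked during collection.
#'
#' @param concentration analyte concentration, ng/mL.
#' @param background negative-control (broad MMP-inhibitor-treated)
#'   concentration, ng/mL.
#' @param volume_mL culture supernatant volume, mL.
#' @param viable_cells viable-cell count at collection.
#' @param duration_h collection time, hours.
#' @param blockade `TRUE` if a receptor-blocking antibody was present.
#' @return `supernatant_measurement` list.
#' @export
supernatant_measurement <- function(concentration, background, volume_mL,
                                    viable_cells, duration_h = 24,
                                    blockade = FALSE) {
  if (missing(background) || is.null(background) || is.na(background))
    stop("a background (negative-control) concentration is required",
         call. = FALSE)
  stopifnot(concentration >= 0, background >= 0, volume_mL > 0,
            viable_cells > 0, duration_h > 0)
  structure(list(concentration = concentration, background = background,
                 volume_mL = volume_mL, viable_cells = viable_cells,
                 duration_h = duration_h, blockade = isTRUE(blockade)),
            class = "supernatant_measurement")
}

#' Ligand release rate from receptor-blocked supernatant accumulation
#'
#' Converts a background-corrected supernatant concentration into the
#' lumped per-cell shedding flux k_Q * P:
#' `rate = max(0, conc - background) * volume * N_A / (mw * cells * time)`
#' in molecules/cell/min. The measurement must have been collected under
#' receptor blockade so capture does not deplete the supernatant; if not,
#' the result carries a capture-confound warning flag.
#'
#' @param m `supernatant_measurement`.
#' @param mw_kDa soluble-ectodomain molecular weight, kDa.
#' @return scalar rate (molecules/cell/min) with attributes `clamped`
#'   (negative net concentration clamped to zero) and `warning`
#'   (`NA` or a capture-confound note).
#' @export
release_rate_from_supernatant <- function(m, mw_kDa) {
  stopifnot(inherits(m, "supernatant_measurement"), mw_kDa > 0)
  net <- m$concentration - m$background
  clamped <- net < 0
  net <- max(0, net)
  ## ng/mL * mL = ng; / (kDa * 1e3 g/mol) -> nmol... work in SI:
  grams <- net * 1e-9 * m$volume_mL            # ng/mL * mL * 1e-9 g/ng
  molecules <- grams / (mw_kDa * 1000) * .N_A
  rate <- molecules / (m$viable_cells * m$duration_h * 60)
  attr(rate, "clamped") <- clamped
  attr(rate, "warning") <- if (!m$blockade)
    "capture confound: measurement was not receptor-blocked" else NA_character_
  rate
}

#' Experimental capture ratio from paired blocked/unblocked measurements
#'
#' The fraction of bulk free ligand as measured: the ratio of
#' background-corrected supernatant accumulation without receptor
#' blockade (capture on) to with blockade (capture off). Each arm is
#' corrected against its own negative control. Ratios above 1
#' (measurement noise) are clipped to 1 with a flag.
#'
#' @param unblocked `supernatant_measurement` with `blockade = FALSE`.
#' @param blocked `supernatant_measurement` with `blockade = TRUE`.
#' @return fraction in \[0, 1\] with attribute `clipped`.
#' @export
capture_ratio <- function(unblocked, blocked) {
  stopifnot(inherits(unblocked, "supernatant_measurement"),
            inherits(blocked, "supernatant_measurement"))
  net_u <- max(0, unblocked$concentration - unblocked$background)
  net_b <- blocked$concentration - blocked$background
  if (net_b <= 0)
    stop("blocked-arm net concentration must be > 0", call. = FALSE)
  ratio <- net_u / net_b
  clipped <- ratio > 1
  ratio <- min(1, ratio)
  attr(ratio, "clipped") <- clipped
  ratio
}

#' Build a calibration curve from bead standards
#'
#' Linear fit of fluorescence signal against known antibody-binding
#' capacity, as used to convert surface staining into absolute receptor
#' numbers per cell.
#'
#' @param signal fluorescence at each calibrator (>= 2 points).
#' @param known known quantities (e.g. binding sites/bead), strictly
#'   increasing.
#' @return `calibration_curve` with slope, intercept, and R^2.
#' @export
calibration_curve <- function(signal, known) {
  if (length(signal) != length(known) || length(signal) < 2)
    stop("need >= 2 matched (signal, known) calibration points",
         call. = FALSE)
  if (any(diff(known) <= 0) || any(diff(order(signal)) < 0))
    stop("calibration points must be strictly increasing in the known ",
         "quantity with monotone signal", call. = FALSE)
  fit <- stats::lm(known ~ signal)
  structure(list(signal = signal, known = known,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 residuals = unname(stats::residuals(fit))),
            class = "calibration_curve")
}

#' Absolute receptor number from a calibrated signal
#'
#' Inverse mapping of a fluorescence signal through a bead standard
#' curve: piecewise-linear interpolation through the calibrators (exact
#' at each calibration point), continued with the edge-segment slope
#' outside the calibrated range. Out-of-range results are flagged as
#' extrapolated; negatives are clamped at zero.
#'
#' @param signal fluorescence value(s).
#' @param curve `calibration_curve`.
#' @return receptors/cell with attribute `extrapolated` (logical per
#'   value).
#' @export
receptor_count_from_calibration <- function(signal, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  s <- curve$signal; k <- curve$known
  n <- length(s)
  val <- stats::approx(s, k, xout = pmin(pmax(signal, s[1]), s[n]))$y
  below <- signal < s[1]; above <- signal > s[n]
  if (any(below))
    val[below] <- k[1] + (signal[below] - s[1]) * (k[2] - k[1]) / (s[2] - s[1])
  if (any(above))
    val[above] <- k[n] + (signal[above] - s[n]) *
      (k[n] - k[n - 1]) / (s[n] - s[n - 1])
  val <- pmax(0, val)
  attr(val, "extrapolated") <- below | above
  val
}

#' Calibrate an autocrine system against measured readouts
#'
#' Wires measured release rates and receptor numbers into the model and,
#' when experimental capture ratios (bulk free-ligand fractions) are
#' supplied, tunes each ligand's K_D by bounded search on log K_D so the
#' simulated free-ligand fraction reproduces the measurement. All other
#' constants stay at their defaults. Each achieved ratio is re-checked by
#' simulation; misfits beyond 0.1 absolute are reported in the
#' `calibration` attribute, never silently accepted.
#'
#' @param rates named numeric vector: per-ligand release rates
#'   (molecules/cell/min); every configured ligand must be present.
#' @param receptor_count receptors/cell (R0), optional.
#' @param capture_ratios optional named numeric vector of measured bulk
#'   free-ligand fractions in \[0, 1\] per ligand.
#' @param config base configuration (defaults to [default_config()]
#'   restricted to the named ligands).
#' @param kd_range search bounds for K_D (molar).
#' @return calibrated `autocrine_system`; attribute `calibration` is a
#'   data.frame (ligand, target, achieved, K_D, at_boundary, ok).
#' @export
calibrate_system <- function(rates, receptor_count = NULL,
                             capture_ratios = NULL,
                             config = NULL,
                             kd_range = c(1e-11, 1e-4)) {
  if (!length(rates) || is.null(names(rates)))
    stop("rates must be a named vector with at least one ligand",
         call. = FALSE)
  if (is.null(config)) {
    known <- intersect(names(rates), c("HBEGF", "AREG"))
    config <- if (length(known) == length(rates)) default_config(names(rates))
    else {
      cfg <- default_config("HBEGF")
      cfg$ligands <- lapply(names(rates), function(nm) {
        l <- cfg$ligands[[1]]; l$name <- nm; l
      })
      cfg
    }
  }
  lig_names <- vapply(config$ligands, function(l) l$name %||% "",
                      character(1))
  missing_rate <- setdiff(lig_names, names(rates))
  if (length(missing_rate))
    stop("no release rate supplied for ligand(s): ",
         paste(missing_rate, collapse = ", "), call. = FALSE)
  for (i in seq_along(config$ligands))
    config$ligands[[i]]$Q_molecules_cell_min <- unname(rates[lig_names[i]])
  if (!is.null(receptor_count))
    config$receptor$R0 <- receptor_count
  sys <- build_system(config)

  cal <- NULL
  if (!is.null(capture_ratios)) {
    if (sys$receptor$R0 <= 0 && any(capture_ratios < 1))
      stop("capture demanded (ratio < 1) but the system has no receptors",
           call. = FALSE)
    rows <- lapply(names(capture_ratios), function(nm) {
      target <- capture_ratios[[nm]]
      path <- paste0("ligands.", nm, ".K_D")
      obj <- function(logkd) {
        s <- set_parameter(sys, path, 10^logkd)
        free_ligand_fraction(s, nm) - target
      }
      lo <- log10(kd_range[1]); hi <- log10(kd_range[2])
      flo <- obj(lo); fhi <- obj(hi)
      at_boundary <- FALSE
      if (flo * fhi > 0) { # target outside achievable range: pin to edge
        logkd <- if (abs(flo) < abs(fhi)) lo else hi
        at_boundary <- TRUE
      } else {
        logkd <- stats::uniroot(obj, c(lo, hi), tol = 1e-3)$root
      }
      sys <<- set_parameter(sys, path, 10^logkd)
      achieved <- free_ligand_fraction(sys, nm)
      data.frame(ligand = nm, target = target, achieved = achieved,
                 K_D = 10^logkd, at_boundary = at_boundary,
                 ok = abs(achieved - target) <= 0.1)
    })
    cal <- do.call(rbind, rows)
    if (any(!cal$ok))
      warning("calibration could not reproduce capture ratio(s) for: ",
              paste(cal$ligand[!cal$ok], collapse = ", "),
              " (see attr(sys, 'calibration'))", call. = FALSE)
  }
  attr(sys, "calibration") <- cal
  sys
}
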