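## Seeded generators for every input the pipeline consumes, each carrying
## a ground-truth sidecar so recovery can be tested without external data.
## All generators are pure functions of (config, seed): the global RNG
## stream is saved and restored around each call.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' A plausible protease x substrate signature for synthetic panels
#'
#' Seven FRET substrates against four sheddases (ADAM8/10/12/17), with
#' partially overlapping specificities: each protease has one or two
#' preferred substrates plus weaker off-target activity, mimicking the
#' overlapping cleavage preferences of the ADAM family. Documented
#' synthetic stand-in, not measured catalytic efficiencies.
#'
#' @return `signature_matrix` (7 substrates x 4 proteases).
#' @export
example_signature <- function() {
  prot <- c("ADAM8", "ADAM10", "ADAM12", "ADAM17")
  subs <- paste0("S", 1:7)
  m <- matrix(c(
    ## ADAM8 ADAM10 ADAM12 ADAM17
    1.00, 0.10, 0.05, 0.20,  # S1
    0.15, 1.20, 0.10, 0.05,  # S2
    0.05, 0.80, 0.30, 0.10,  # S3
    0.10, 0.05, 1.10, 0.15,  # S4
    0.20, 0.15, 0.70, 0.40,  # S5
    0.05, 0.10, 0.15, 1.00,  # S6
    0.30, 0.25, 0.20, 0.60   # S7
  ), nrow = 7, byrow = TRUE, dimnames = list(subs, prot))
  signature_matrix(m)
}

#' Ground truth for a synthetic cue-signal-response study
#'
#' Draws latent per-condition protease activities and a
#' protease-to-substrate coupling matrix with a designated dominant
#' protease per shed analyte. The condition panel mirrors a
#' growth-factor/cytokine stimulation design: `n_cues` cues, each with
#' and without receptor blockade.
#'
#' @param seed integer seed.
#' @param n_cues number of stimulation cues (conditions = 2 * n_cues
#'   with blockade arms).
#' @param proteases protease labels.
#' @param analytes named character vector mapping each shed analyte to
#'   its true dominant protease, e.g. `c(HBEGF = "ADAM12")`.
#' @param coupling_strength dominant coupling relative to off-target
#'   couplings.
#' @param noise_cv multiplicative noise CV used downstream.
#' @return `csr_truth` list: `activities` (conditions x proteases),
#'   `coupling` (proteases x analytes), `seed`, `noise_cv`.
#' @export
csr_ground_truth <- function(seed, n_cues = 8,
                             proteases = c("ADAM8", "ADAM10", "ADAM12",
                                           "ADAM17"),
                             analytes = c(HBEGF = "ADAM12",
                                          TNFR1 = "ADAM17",
                                          MET = "ADAM10"),
                             coupling_strength = 5,
                             noise_cv = 0.1) {
  .with_seed(seed, {
    conds <- as.vector(outer(paste0("cue", seq_len(n_cues)),
                             c("mab225", "open"), paste, sep = "_"))
    acts <- matrix(stats::runif(length(conds) * length(proteases), 0.2, 2),
                   length(conds), length(proteases),
                   dimnames = list(conds, proteases))
    coup <- matrix(stats::runif(length(proteases) * length(analytes),
                                0.05, 0.2) * coupling_strength / 5,
                   length(proteases), length(analytes),
                   dimnames = list(proteases, names(analytes)))
    for (a in names(analytes)) coup[analytes[[a]], a] <- coupling_strength
    structure(list(activities = acts, coupling = coup, seed = seed,
                   noise_cv = noise_cv, analytes = analytes),
              class = "csr_truth")
  })
}

#' Generate a synthetic FRET cleavage panel
#'
#' Fluorescence grows linearly in time from an offset with slope
#' `signature %*% activities`, plus additive Gaussian noise scaled to the
#' panel's signal range — the idealization under which the rate of
#' fluorescence increase is the cleavage rate.
#'
#' @param truth `csr_truth`.
#' @param signature `signature_matrix`.
#' @param timepoints acquisition times (minutes; default 5 points over
#'   3 h).
#' @param replicates biological replicates (default 4).
#' @param noise_sd additive noise SD as a fraction of the signal range
#'   (default `truth$noise_cv`).
#' @param offset baseline fluorescence (AU).
#' @param seed seed for the noise draw (default derived from the truth
#'   seed).
#' @return `fret_panel` with attribute `truth`.
#' @export
gen_fret_panel <- function(truth, signature = example_signature(),
                           timepoints = seq(0, 180, length.out = 5),
                           replicates = 4, noise_sd = truth$noise_cv,
                           offset = 100, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "csr_truth"))
  if (any(truth$activities < 0)) stop("activities must be >= 0")
  slopes <- truth$activities %*% t(signature[, colnames(truth$activities),
                                             drop = FALSE])
  .with_seed(seed, {
    nc <- nrow(slopes); ns <- ncol(slopes); nt <- length(timepoints)
    arr <- array(NA_real_, c(nc, ns, replicates, nt),
                 dimnames = list(rownames(slopes), colnames(slopes),
                                 seq_len(replicates), timepoints))
    range_sig <- max(slopes) * max(timepoints)
    for (r in seq_len(replicates)) {
      clean <- offset + outer(as.vector(slopes), timepoints)
      noise <- stats::rnorm(length(clean), 0, noise_sd * range_sig)
      arr[, , r, ] <- array(clean + noise, c(nc, ns, nt))
    }
    p <- fret_panel(arr, timepoints)
    attr(p, "truth") <- truth
    p
  })
}

#' Generate a synthetic shedding (supernatant ELISA) panel
#'
#' Per-cell shedding responses are linearly coupled to the latent
#' protease activities (`coupling' columns), plus an assay baseline; raw
#' concentrations are produced by multiplying back through log-normally
#' distributed cell counts and adding the baseline, with multiplicative
#' log-normal noise (CV `truth$noise_cv`). A matching
#' metalloproteinase-inhibited background column and the cell counts are
#' returned, in the exact shape [normalize_responses()] ingests.
#'
#' @param truth `csr_truth`.
#' @param volume_mL supernatant volume.
#' @param baseline assay background level (concentration units).
#' @param scale per-cell response scale factor.
#' @param mean_cells log-normal location for viable-cell counts.
#' @param seed noise seed.
#' @return list: `raw` (conditions x analytes), `background`, `cells`,
#'   `volume_mL`, `truth`, `true_responses` (noise-free per-cell).
#' @export
gen_shedding_panel <- function(truth, volume_mL = 0.1, baseline = 5,
                               scale = 1, mean_cells = 1e5,
                               seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "csr_truth"))
  per_cell <- scale * truth$activities %*%
    truth$coupling[colnames(truth$activities), , drop = FALSE]
  .with_seed(seed, {
    nc <- nrow(per_cell)
    cells <- stats::rlnorm(nc, log(mean_cells), 0.1)
    names(cells) <- rownames(per_cell)
    conc_clean <- sweep(per_cell, 1, cells / volume_mL, `*`)
    cv <- truth$noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(stats::rlnorm(length(conc_clean), -sdlog^2 / 2, sdlog),
                    nc, ncol(conc_clean))
    raw <- conc_clean * noise + baseline
    bg_noise <- stats::rlnorm(nc * ncol(conc_clean), -sdlog^2 / 2, sdlog)
    background <- matrix(baseline * bg_noise, nc, ncol(conc_clean),
                         dimnames = dimnames(conc_clean))
    dimnames(raw) <- dimnames(conc_clean)
    list(raw = raw, background = background, cells = cells,
         volume_mL = volume_mL, truth = truth, true_responses = per_cell)
  })
}

#' Generate a synthetic receptor-blockade capture experiment
#'
#' Simulates the paired supernatant-accumulation experiment through the
#' compartmental model: 24 h accumulation with and without receptor
#' blockade, converted to immunoassay concentrations (ng/mL) with
#' multiplicative log-normal noise. The model's true free-ligand
#' fraction is recorded in the sidecar.
#'
#' @param sys `autocrine_system`.
#' @param ligand ligand name.
#' @param noise_cv multiplicative noise CV (0 for noiseless closure
#'   tests).
#' @param seed noise seed.
#' @param background assay background (ng/mL) added to both arms.
#' @return list: `unblocked`, `blocked` ([supernatant_measurement]s),
#'   `truth` (true free fraction, capture fraction, seed).
#' @export
gen_capture_experiment <- function(sys, ligand = names(sys$ligands)[1],
                                   noise_cv = 0.1, seed = 1L,
                                   background = 0.05) {
  lig <- sys$ligands[[ligand]]
  arm <- function(blockade) {
    s <- set_parameter(sys, "receptor.blockade_fraction", blockade)
    tr <- simulate_system(s)
    b <- .ligand_balance(tr, ligand)
    n <- length(b$free)
    molecules_per_cell <- b$free[n] + b$antibody[n]
    total_g <- molecules_per_cell * sys$geometry$n_cells / .N_A *
      lig$mw_kDa * 1000
    total_g / (sys$geometry$well_volume_L * 1e3) * 1e9 # ng/mL
  }
  conc_open <- arm(0)
  conc_blk <- arm(1)
  tr <- simulate_system(sys)
  truth <- list(free_fraction = conc_open / conc_blk,
                capture_fraction = capture_fraction(tr, ligand),
                seed = seed, noise_cv = noise_cv)
  .with_seed(seed, {
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    fuzz <- function(x) if (sdlog > 0)
      x * stats::rlnorm(1, -sdlog^2 / 2, sdlog) else x
    mk <- function(conc, blockade) supernatant_measurement(
      concentration = fuzz(conc) + background, background = background,
      volume_mL = sys$geometry$well_volume_L * 1e3,
      viable_cells = sys$geometry$n_cells, duration_h = 24,
      blockade = blockade)
    list(unblocked = mk(conc_open, FALSE), blocked = mk(conc_blk, TRUE),
         truth = truth)
  })
}

#' Generate a synthetic inhibitor dilution-series assay
#'
#' Initial velocities from either the hyperbolic inhibition model or the
#' tight-binding (Morrison) model at the stated enzyme concentration,
#' over a serial-dilution dose grid, with multiplicative noise. The
#' generating parameters ride along as the truth sidecar.
#'
#' @param k_i_nM true inhibition constant (nM); for the hyperbolic model
#'   this is the true IC50.
#' @param model `"hyperbolic"` or `"morrison"`.
#' @param enzyme_conc_nM enzyme concentration (nM).
#' @param top_dose_nM top of the dilution series (nM).
#' @param n_doses dilution points (default 6).
#' @param dilution serial dilution factor (default 3).
#' @param replicates replicates per dose (default 2).
#' @param v0 uninhibited velocity (AU/min).
#' @param noise_cv multiplicative noise CV.
#' @param seed noise seed.
#' @param substrate_conc_uM substrate concentration (uM).
#' @param enzyme enzyme label.
#' @return `inhibition_assay` with attribute `truth`.
#' @export
gen_dose_response <- function(k_i_nM, model = c("hyperbolic", "morrison"),
                              enzyme_conc_nM = 5, top_dose_nM = 10000,
                              n_doses = 6, dilution = 3, replicates = 2,
                              v0 = 1, noise_cv = 0.05, seed = 1L,
                              substrate_conc_uM = 15, enzyme = "enzyme") {
  model <- match.arg(model)
  doses <- c(0, top_dose_nM / dilution^((n_doses - 1):0))
  frac <- if (model == "hyperbolic") k_i_nM / (k_i_nM + doses)
  else .morrison_frac(doses, enzyme_conc_nM, k_i_nM)
  clean <- rep(v0 * frac, each = replicates)
  all_doses <- rep(doses, each = replicates)
  .with_seed(seed, {
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    noisy <- if (sdlog > 0)
      clean * stats::rlnorm(length(clean), -sdlog^2 / 2, sdlog) else clean
    a <- inhibition_assay(all_doses, noisy, enzyme_conc_nM,
                          substrate_conc_uM, enzyme = enzyme)
    attr(a, "truth") <- list(k_i_nM = k_i_nM, model = model, v0 = v0,
                             noise_cv = noise_cv, seed = seed)
    a
  })
}
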