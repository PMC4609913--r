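# autoloop

Quantitative analysis of autocrine growth-factor loops: why decoy
antibodies fail against high-affinity, locally-captured ErbB ligands,
and how sheddase inhibition sidesteps the problem.

Epithelial cells that co-express EGFR and its proteolytically shed
ligands (HB-EGF, amphiregulin, TGFα, ...) signal to themselves in a
tight spatial loop: a ligand shed into the thin fluid layer over the
cell surface may rebind a receptor within micrometers of its release
site, or escape by diffusion into the bulk medium. Which fate dominates
is set by the ligand-receptor dissociation constant K_D, the ligand's
effective diffusivity, and receptor trafficking — and it decides whether
a ligand is even reachable by a soluble "decoy" antibody.

`autoloop` provides:

* **A three-compartment ODE model** of this loop, matched to a 100 uL
  culture well: a 2 um boundary layer over the cell surface (V_S), a
  50 um layer over the monolayer (V_B), and the remaining bulk (V_BB).
  Per cell, receptors follow

      dR/dt = q_R − k_t·R − k_on·L_S·R + k_off·C
      dC/dt = k_on·L_S·R − (k_off + k_e)·C

  with ligand shed into V_S at the lumped flux k_Q·P (molecules per
  cell per minute) and moved between compartments by diffusive transport
  Δ_ij = D·A/δ_ij. Optional species: a soluble decoy antibody that
  sequesters ligand 1:1 (default K_D = 0.1 nM), and a reversible
  protease inhibitor that scales shedding by the free-enzyme fraction.
  The headline readouts are the cumulative **capture fraction**
  (internalized / released over 24 h) and total ligand-receptor
  complexes at 24 h.
* **Dose-response machinery**: decoy and inhibitor sweeps, IC50 by
  log-linear interpolation, and parameter sweeps (affinity,
  diffusivity) with provenance.
* **Parameterization from bench readouts**: shedding rates from
  receptor-blocked supernatant ELISA, receptor numbers from bead
  calibration curves, capture ratios from paired ±blockade
  measurements, and K_D calibration against those ratios.
* **A cue-signal-response pipeline**: cleavage rates from FRET-substrate
  panels (OLS slopes), non-negative least-squares deconvolution of
  specific ADAM activities through a catalytic-efficiency signature
  matrix, per-cell response normalization with background correction,
  and protease×substrate Pearson correlation maps with two-tailed
  t-test p-values and sheddase rankings.
* **Inhibitor potency fitting**: initial rates, hyperbolic and
  tight-binding (Morrison) dose-response fits, K_i with optional
  K_M correction, no-inhibition detection, and specificity panels.
* **Seeded synthetic-data generators** for every input, each carrying a
  ground-truth sidecar, so the full pipeline is testable end to end.

## Worked example

```r
library(autoloop)

sys <- build_system(default_config())   # two-ligand 12Z-like system
tr  <- simulate_system(sys, hours = 24)
tr
#> Autocrine trajectory: 241 time points over 24 h, 13 species
#>   HBEGF: released 1.44e+04 molecules/cell, capture fraction 0.905
#>   AREG: released 1.01e+05 molecules/cell, capture fraction 0.184
```

The high-affinity ligand (K_D = 1 nM) is almost entirely recaptured by
surface EGFR before it can escape the cell-surface boundary layer; the
low-affinity ligand (K_D = 100 nM) mostly diffuses into the bulk. That
asymmetry translates directly into decoy-antibody efficacy at the
typical 10 ug/mL (67 nM) dose:

```r
dose <- 10e-6 / 150000            # 10 ug/mL of a 150 kDa IgG, in M
for (lg in c("HBEGF", "AREG")) {
  cfg <- default_config(lg); cfg$decoy <- default_decoy()
  cur <- decoy_dose_response(build_system(cfg), c(0, dose))
  cat(lg, "complex reduction:", round(max(cur$response), 3), "\n")
}
#> HBEGF complex reduction: 0.033
#> AREG complex reduction: 0.196
```

A six-fold difference: the decoy barely touches the high-affinity loop.
A protease inhibitor acting on the shedding step has no such
dependence — its IC50 sits near its K_i regardless of ligand affinity:

```r
cfg <- default_config("HBEGF"); cfg$inhibitor <- default_inhibitor()
sys <- build_system(cfg)
ic50_from_curve(inhibitor_dose_response(sys, dose_grid(sys$inhibitor$K_i)))
#> IC50 = 4.162e-07 M (bracketed; log-linear interpolation)
```

(K_i = 430 nM here, the measured potency scale of the recombinant
ADAM12 prodomain.)

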