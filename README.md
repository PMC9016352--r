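# hpslab

Coarse-grained slab simulations and phase analysis of TDP-43
low-complexity-domain condensates.

## What this package is for

TDP-43 aggregates in ALS and frontotemporal dementia carry a diagnostic
mark: hyperphosphorylation of a cluster of C-terminal serines inside the
protein's low-complexity domain (LCD, residues 261–414).  Whether those
phosphates *drive* aggregation or *oppose* it is, computationally, a
question about how extra negative charge changes the balance of weak
interactions that lets LCDs demix into protein-rich condensates
(liquid–liquid phase separation).  `hpslab` provides the modelling and
quantification toolkit for that question, for people who study condensate
biophysics in R:

- **sequence/variant machinery** — the canonical 414-residue TDP-43
  sequence as a validated fixture, phosphomimetic (S→D), control (S→A) and
  phosphoserine (pS) variants at the canonical 2/5/12 site sets, and
  Henderson–Hasselbalch net-charge calculations;
- **an HPS coarse-grained force field and Langevin engine** — one bead per
  residue, Ashbaugh–Hatch hydrophobicity-scaled interactions plus
  Debye–Hückel electrostatics, BAOAB integration, and the slab-coexistence
  protocol (compact growth → equilibration → box extension → production);
- **phase analysis** — z-density profiles, coexisting dense/dilute
  concentrations, transfer free energies, condensate detection, variant
  ranking;
- **contact and solvation analysis** — residue contact maps (fixed 4.5 Å
  or 2^(1/6)σ rules, i±2 exclusion), difference maps, amino-acid-type
  resolved contact profiles, water-coordination histograms;
- **wet-lab quantification formulas** — sedimentation S/(S+C) ratios,
  FRAP normalization and AUC, droplet segmentation with roundness
  (4·area/(π·major²)) and circularity filters;
- **seeded synthetic-fixture generators** with serialized ground truth for
  every analysis operator.

## The model in brief

Each residue is one bead with mass, integer charge, diameter σ and
hydrophobicity λ.  Nonbonded beads interact through the Ashbaugh–Hatch
potential

    Φ(r) = Φ_LJ(r) + (1−λij)·ε   for r ≤ 2^(1/6)·σij
    Φ(r) = λij·Φ_LJ(r)           for r >  2^(1/6)·σij

(σij, λij arithmetic means; ε = 0.2 kcal/mol) plus screened electrostatics
Φ_el(r) = qiqj·e²·exp(−r/κ⁻¹)/(4πε₀Dr) with κ⁻¹ ≈ 9.9 Å at 100 mM and
310 K.  Consecutive beads are bonded harmonically (k = 10 kJ/mol/Å²,
r₀ = 3.8 Å).  Coexistence is read from slab simulations: the z-density
profile gives c_dense and c_dilute, and the transfer free energy is
ΔG_trans = −RT·ln(c_dense/c_dilute).

## Worked example: net charge of the variant series

```r
library(hpslab)

full <- tdp43_sequence()          # canonical 414-aa TDP-43, bundled
specs <- tdp43_variant_specs()    # Wt, 2D/5D/12D, 2A/5A/12A, 2pS/5pS/12pS

round(net_charge(full), 1)
#> [1] -4.1
round(net_charge(build_variant(full, specs[["12D"]])), 1)
#> [1] -16.1
round(net_charge(build_variant(full, specs[["12pS"]])), 1)
#> [1] -28.1
```

At physiological pH the wild-type protein carries a net charge of −4.1 e;
twelve phosphomimetic aspartates add ≈ −12, and twelve phosphoserines
(−2 each) add −24 — the charge axis along which condensation weakens.

## Worked example: a reduced slab simulation

```r
ff  <- hps_forcefield()
lcd <- extract_region(tdp43_sequence(), 261, 414)   # 154 residues

init <- initialize_compact(10, lcd, ff, sub_box = c(110, 110, 160), seed = 1)
init <- minimize_energy(init, ff)
sch  <- simulation_schedule(seed = 1, stride = 2500, phases = list(
  list(label = "equilibration", n_steps = 10000,  box_z = NULL),
  list(label = "production",    n_steps = 60000,  box_z = 700)))
traj <- run_langevin(init, ff, sch)

prof <- density_profile(traj, ff, n_bins = 70, phases = "production")
phase_concentrations(prof, dense_halfwidth = 50, dilute_margin = 250)
#> $c_dense
#> [1] 190.2
#> $c_dilute
#> [1] 0.000
detect_condensate(prof, 10, 250)
#> [1] TRUE
```

A ten-chain wild-type LCD slab keeps a dense condensate (~190 mg/mL here)
coexisting with an almost empty dilute phase.  `run_phase_pipeline()`
drives the same loop over a whole variant panel with replicates and
ranking; `schedule_preset("desk")` and `schedule_preset("full")` hold the
larger protocols (the full-scale one — 100 chains, 212 × 212 × 2800 Å,
several µs — is cluster-scale and not meant for a laptop).

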