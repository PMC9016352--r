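---
title: "Coarse-grained phase-separation modelling of the TDP-43 low-complexity domain"
author: "hpslab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained phase-separation modelling of the TDP-43 low-complexity domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

TDP-43, the major aggregating protein of ALS and frontotemporal dementia, is
hyperphosphorylated in disease on a cluster of C-terminal serines inside its
low-complexity domain (LCD, residues 261–414).  Whether those phosphate
groups promote or suppress condensation is a question about the balance of
weak multivalent interactions that drive liquid–liquid phase separation
(LLPS).  `hpslab` implements the computational side of that question: a
residue-level coarse-grained model of LCD condensation, slab-coexistence
analysis, contact and solvation analyses, sequence/charge arithmetic for the
phosphomimetic (S→D), control (S→A) and phosphoserine (pS) variant series,
and the image/trace quantification formulas used by the accompanying wet-lab
assays.

## Sequences, variants and net charge

The canonical 414-residue human TDP-43 sequence (UniProt Q13148) ships as a
FASTA fixture.  The transcription was validated against independent
constraints: length 414, average mass 44,739.4 Da (the database lists
44,740), the LCD span 261–414 being 154 residues, every canonical
phosphosite (S373, S375, S379, S387, S389, S393, S395, S403, S404, S407,
S409, S410) being a serine, and position 408 being a lysine.  Variant
construction is pure residue substitution at full-length coordinates; the
site sets are nested (2 ⊂ 5 ⊂ 12).

Net charge uses Henderson–Hasselbalch fractional charges.  The default pKa
set is the Scripps Protein Calculator set (D/E 4.4, C 8.5, Y 10.0, H 6.5,
K 10.0, R 12.0, N-term 8.0, C-term 3.1), *with termini included*, and
"physiological pH" is taken as 7.4.  These three conventions were selected
jointly because they reproduce the reference values −4.1 (Wt), −16.1 (12D)
and −28.1 (12pS) to one decimal; widely used alternatives (EMBOSS,
Lehninger, Sillero, Bjellqvist, Grimsley, IPC) do not.  Phosphoserine
contributes −2 exactly in the default `fixed_minus2` mode — the arithmetic
implied by −4.1 → −28.1 — with a `henderson` mode available that titrates
the second phosphate ionization (default pKa 6.0).  A consequence worth
stating: the exact 12D−Wt difference is 12 × (−0.999001) = −11.988, not
−12.000, because aspartate is very slightly protonated at pH 7.4 under this
set; the phospho differences (−2 per site) are exact.

## The energy model

One bead per residue.  Parameters per bead type (mass, integer charge,
diameter σ, hydrophobicity λ) follow the HPS model (Dignon et al. 2018,
PLoS Comput Biol), with λ on the Kapcha–Rossky-derived scale.  The
phosphoserine bead is parameterized in-package: charge −2, mass 167.06 Da
(Ser + HPO3), σ = 5.97 Å (serine enlarged by the phosphate volume), and
λ = 0.15.  The λ value follows the scale's own atom-fraction logic:
serine (0.595) loses about twice the decrement that the S→D step shows
for a carboxylate when it instead gains a dianionic phosphate, which
keeps phosphoserine below aspartate (0.378) — a doubly charged group
must not come out more hydrophobic than a singly charged one.  The pair potential is the Ashbaugh–Hatch form

$$\Phi(r) = \begin{cases} \Phi_{LJ}(r) + (1-\lambda_{ij})\,\epsilon & r \le 2^{1/6}\sigma_{ij} \\ \lambda_{ij}\,\Phi_{LJ}(r) & r > 2^{1/6}\sigma_{ij}\end{cases}$$

with arithmetic mixing of σ and λ, so the repulsive core survives at λ = 0
and both branches meet at −λ<sub>ij</sub>ε.  Electrostatics is Debye–Hückel:
$\Phi_{el}(r) = q_i q_j e^2 \exp(-r/\kappa^{-1})/(4\pi\varepsilon_0 D r)$,
with the screening length computed from temperature, dielectric and ionic
strength.  Consecutive beads are joined by harmonic bonds
$k(r-r_0)^2/2$ and excluded from the nonbonded sums.

Global defaults (all overridable): ε = 0.2 kcal/mol = 0.8368 kJ/mol,
k = 10 kJ/(mol Å²), r₀ = 3.8 Å, D = 80, ionic strength 100 mM, T = 310 K
(κ⁻¹ ≈ 9.9 Å), cutoffs 25 Å (van der Waals) and 35 Å (electrostatics),
plain truncation.  Truncation rather than shifting keeps the switch-point
identity Φ(2^{1/6}σ) = −λε exact; the residual discontinuity at the cutoff
is below 10⁻³ ε and irrelevant for thermostatted dynamics (the
energy-conservation test uses a system that never spans the cutoff).
Internal units are Å, kJ/mol, g/mol, ps.

Correctness is defined by equality: the cell-list/neighbor-list energy must
match an all-pairs double loop (and an independent R oracle) to 1 part in
10⁸, and analytic forces must match central finite differences to 10⁻⁴
relative error on configurations without extreme overlaps.

## Dynamics and the slab protocol

Langevin dynamics with the BAOAB splitting, timestep 10 fs, friction
0.01 ps⁻¹.  The weak friction is deliberate: in an implicit solvent the
friction sets only the rate of configurational sampling, not the sampled
ensemble, so low values accelerate equilibration.  Velocities are drawn
from Maxwell–Boltzmann at the target temperature; the random stream is a
splitmix64-seeded xoshiro256++ generator, so a (seed, inputs) pair gives
bit-identical trajectories on one platform.  Calibration is tested against
closed forms: mean kinetic temperature of a free bead within three standard
errors of 310 K, and the bond-length distribution of a bonded dimer against
the r²-weighted Boltzmann factor of the harmonic bond
(Kolmogorov–Smirnov).

The slab protocol has three stages: (1) chains grown as self-avoiding walks
in a compact box (bonds exactly r₀, non-bonded beads no closer than
0.8 min σ), relaxed by a clamped steepest-descent minimizer; (2)
equilibration in the compact box; (3) extension of the box along z with the
condensate recentered (chains are first unwrapped so no bond spans the old
periodic boundary — a subtlety that otherwise injects catastrophically
stretched bonds), followed by constant-volume production.  Slab coexistence
requires fixed volume, which is why the engine is NVT-only.

Three presets are shipped.  `full` is the full-scale protocol (100 chains
of the 154-residue LCD, 212 × 212 × 2800 Å, ≥ 5.8 µs production): it is the
condition under which the reference phase behavior was established and is
cluster-scale.  `desk` (50 chains, 160 × 160 × 1200 Å, 2 × 10⁶ steps) is a
single-workstation reduction.  `mini` (10 chains, 110 × 110 × 700 Å,
1.5 × 10⁵ production steps) is a minutes-scale smoke protocol; the test
suite runs an even smaller 6-chain variant of it (next section) and
shortens runs further where only plumbing is under test.  Below `desk`
scale no quantitative coexistence concentration is claimed — the
directional contrast between variants is the observable.

## Phase analysis

Per frame, bead masses are binned along z and the profile is recentered.
Centering first locates the densest 100-Å sliding window under periodic
wrap, then refines with a mass-weighted circular-mean pass — the refinement
matters because on a flat-topped slab every window inside the plateau is
equally dense and the argmax tie-break would otherwise mis-center wide
slabs by up to half the plateau width.  Concentrations are in mg/mL
(1 Da/Å³ = 1660.54 mg/mL), so the profile integrates to the total protein
mass; that conservation is asserted in tests.

`c_dense` is the mean concentration within 50 Å of the slab center,
`c_dilute` the mean beyond 250 Å (both windows configurable; the defaults
mirror common coexistence workflows since the reference analysis does not
state its windows).  The transfer free energy is
$\Delta G_{trans} = -RT\,\ln(c_{dense}/c_{dilute})$ with R = 8.3145
J/(mol K).  A condensate is declared when the peak bin is at least 10× the
dilute mean.  Variant ranking sorts by ascending c_dilute with dissolved
variants last; c_dilute values within a relative tolerance (default 0.25 —
a design parameter, since the reference ranking's "~" carries no stated
tolerance) are reported as tied.

Recovery is validated on synthetic slabs drawn from a planted tanh profile:
across 20 log-uniform density ratios in [10, 10⁴], c_dense and c_dilute are
recovered within 5% and ΔG within 0.2 kJ/mol.  Fixture sizes follow a
power rule computed beforehand: the dilute window must collect ≳3000
samples so the counting noise on ΔG (≈ RT/√N) stays near 0.05 kJ/mol, four
times below the tolerance being asserted.

## Contact and solvation analysis

Two contact rules are implemented: a fixed 4.5 Å bead-distance cutoff (the
Martini-style analysis convention; the package analyses such trajectories
but does not generate them) and the HPS rule r < 2^{1/6}σ<sub>ij</sub>.
Both are strict inequalities.  Intra-chain pairs separated by ≤ 2 residues
are excluded and flagged absent (NA), not zero.  For an inter-chain residue
pair the probability denominator is frames × unordered chain pairs, so a
pair planted in every frame scores exactly 1; intra-chain events are
tallied separately (denominator frames × chains) and the combined "both"
mode weights by total opportunities.  Difference maps (e.g. Wt − 12D) are
entrywise with NA propagation and are antisymmetric by construction.
Type-resolved profiles tally contacts of a source selection (e.g. the 12
phosphosites) by partner residue type, normalized to sum to 1; an empty
profile is returned with an explicit `no_contacts` flag rather than an
error.  Solvation histograms count solvent particles within 5 Å of selected
residues; solvent comes from fixture generators or external trajectories,
never from the implicit-solvent engine itself.

## Wet-lab quantification formulas

Sedimentation: S/(S+C) (identical form for S/(S+I) RIPA fractionations).
FRAP: I(t) = (ROI1 − ROI3)/(ROI2 − ROI3), normalized to the mean of a
configurable prebleach window (default 1 frame); areas under the recovery
curve are trapezoidal.  Droplets: difference-of-Gaussians bandpass (small
σ = 1 px, large σ = 20 px — the named 20-px bandpass does not define its
kernel, so a DoG surrogate is used and only scale-level properties are
asserted), Otsu threshold (the reference thresholds were manual),
connected components, then roundness = 4·area/(π·major_axis²) — the
inverse aspect ratio, 1.0 for discs, 0.5 for 2:1 ellipses — and
perimeter-based circularity = 4π·area/perimeter², with the standard
filters circularity ≥ 0.3 and area ≥ 3 px.  Both shape measures are kept
because they are distinct quantities that are easily conflated.

## What the synthetic generators emulate — and what they do not

Every analysis operator is validated against seeded generators whose ground
truth is serialized alongside the fixture: tanh slabs with known
coexistence densities, trajectories with planted contacts at exact
distances, frames with exact planted water-coordination counts, exponential
FRAP recoveries with known plateau, and anti-aliased ellipse images with
known axes.  These fixtures establish that the operators compute the right
quantity from well-defined input.  They deliberately do not emulate
correlated frames, realistic interfacial fluctuations, microscope
point-spread functions or camera noise statistics, so passing them says
nothing about, for example, the statistical efficiency of the estimators on
strongly autocorrelated production trajectories — that is what the
reduced-scale simulation tests probe.

## Reduced-scale phase behavior: design choices and limitations

The central in-silico contrast — S→A stabilizes, full phosphorylation
destabilizes and ultimately dissolves — is probed at reduced scale with a
pre-assembled condensate per variant.  The test-suite scale uses 6 chains
of the 154-residue LCD in a 90 × 90 × 600 Å slab, 0.5–1.2 ns production,
friction lowered to 0.005 ps⁻¹ (faster configurational sampling of the
same ensemble) and three seeds per variant.  What this scale shows
reliably, established through design pilots: condensate *retention* for
Wt, 12A and 12D; an essentially empty dilute phase for every variant
(evaporation events are rare on nanosecond trajectories, so dilute-axis
orderings appear as ties); and *weakened interchain cohesion* of the
fully phosphorylated chains — fewer interchain residue contacts per chain
(2^{1/6}σ rule) than the S→A-stabilized and wild-type chains, with
dense-phase swelling on longer runs.  What it cannot show: complete
dissolution of the 12pS condensate ("no clear peak"), which in this model
is an activated, microsecond-scale process; in nanosecond realizations a
pre-assembled 12pS condensate is swollen and occasionally leaking but
still present.  The suite states that full-scale claim as its own check,
which fails at the test scale by design honesty — the `desk` (20 ns) and
`full` (µs) presets are the protocols under which it is meant to be
evaluated.  Quantitative saturation concentrations likewise belong to the
larger presets; none are asserted at test scale.

## Numerical choices, edge cases

Tie-breaks and degenerate inputs follow explicit contracts: inverted
region bounds, non-serine substitution sites, zero/negative concentrations
in ΔG, overlapping analysis windows, images without components (empty
table, not an error), rejection-sampling failure (error, never a silently
degraded distribution).  The minimizer clamps per-bead displacement to
0.2 Å per iteration and stops at a force ceiling of 10 kJ/mol/Å, which is
small compared to thermal forces at 310 K.  The Verlet skin is 3 Å with a
max-displacement rebuild trigger at skin/2; neighbor-list correctness is
defined by equality with brute force, not by any particular binning scheme
(boxes with fewer than three cells per dimension deduplicate the wrapped
stencil).  The electrostatic kernel in the integrator uses an 8192-point
tabulated screened-Coulomb with linear interpolation; the energy-reporting
path uses the exact expression, and agreement is covered by the
force/finite-difference and NVE tests.

## Known limitations

Single platform determinism only (floating-point reduction order is
fixed, but results are not portable bit-for-bit across compilers).  No
replica exchange, no pressure coupling, no explicit-solvent engines: the
Martini-style and atomistic analyses in the literature are supported only
as analysis operators over externally produced or synthetic trajectories.
The HPS phosphoserine parameters are a package-level assignment (charge
−2 is the physically dominant term); users with a preferred published
phospho-parameter table can supply it as a CSV.
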