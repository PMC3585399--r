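---
title: "Reduced ligand fluctuations as an entropic ion-selectivity mechanism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced ligand fluctuations as an entropic ion-selectivity mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rlfep)
```

This vignette is the package's own account of its science: the model systems
it simulates, the free-energy machinery it runs on them, the parameters that
matter, and the numerical and design choices behind both. Nothing stated here
as an empirical result goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The question and the model

Three "cavity" pictures are commonly invoked to explain how an ion-binding
site distinguishes Li⁺, Na⁺ and K⁺: a *rigid* cavity (ligand positions fixed
regardless of the ion), a *strained* cavity (positions adjust, at an
energetic cost), and *reduced ligand fluctuations* (RLF): positions adjust
freely and at no cost, and only the **amplitude of thermal motion** of the
coordinating groups is restricted. The package isolates the third mechanism
in the cleanest setting that still has real interactions.

A model site is a single fixed cation at the origin plus `n = 4..8` copies
of a small dipolar ligand. The abstract ligand is formaldehyde-like (C +0.5 e,
O −0.5 e, H 0.0 e, harmonic bonds and angles, 12-6 Lennard-Jones on every
atom); transporter-site models replace it with carbonyl, hydroxyl and
carboxylate fragments in the compositions of the two sodium sites of the
leucine transporter LeuT and of the aspartate transporter Glt_Ph. Two
restraints define the site:

* a **one-sided spherical wall** `0.5 k_wall (|r| − 3.5)²` (k_wall = 100
  kcal/mol/Å², exactly zero inside 3.5 Å) on every coordinating oxygen,
  which controls how many ligands stay near the ion without fixing their
  positions, and
* optional **harmonic anchors** `0.5 k_f |r − r₀|²` on *every ligand atom*,
  whose force constant k_f is the experimental dial: k_f = 0 is the freely
  fluctuating site, k_f = 10³ kcal/mol/Å² essentially freezes the ligands.

The crucial condition is *where* the anchors sit. For each ion, the package
measures the optimal ion–oxygen distance `R_opt` as the first peak of the
ion–oxygen radial distribution function of the **unconstrained** (wall-only)
site, and anchors that ion's cage at its own `R_opt` geometry. Because every
ion gets its own optimal anchor set, tightening k_f introduces no strain;
anything it does to selectivity is the RLF mechanism. Anchoring both ions at
one ion's geometry — the strained-cavity comparison — is available as a
deliberate, flagged mode (`allow_strain = TRUE` / `strain_ion =` in
`rlf_curve()`), and is refused otherwise.

## 2. The thermodynamic cycle

Selectivity is quantified as the free energy of exchanging two ions between
the model site and bulk water. For a pair (A, B) the package assembles

```
ddG_exchange(A, B) = dG_out(B) + dG_site(B→A) − ddG_hydr(B→A) − dG_out(A)
```

* `dG_out(M)`: the **restraint morph** — a dual-topology FEP leg between the
  anchored ligand set (λ = 0, fully interacting, anchors on) and a duplicate
  free set (λ = 1, wall only). One set is annihilated while the other is
  exnihilated; both endpoints are n ligands coordinating M, so the leg
  measures exactly the free energy of releasing the positional constraint.
* `dG_site(B→A)`: the **ion morph** in the fluctuating (wall-only) site; the
  ion's Lennard-Jones parameters are interpolated between species while the
  charge stays +1.
* `ddG_hydr(B→A)`: the bulk-water leg, taken from the packaged hydration
  free energies of the ion models (only differences are used).

Positive `ddG_exchange` means B is preferred in the site. The RLF component
is the k_f-dependent part, `ddG_RLF(k_f) = dG_out(B) − dG_out(A)`, which is
identically zero at k_f = 0 (both constraint legs vanish) and independent of
the ion-morph and hydration legs. Each dual-topology leg carries a
ghost-state contribution (the decoupled anchored set is a translationally
invariant harmonic gas, the decoupled free set a wall-confined gas); these
terms are identical across ions and cancel exactly in both `ddG_RLF` and
`ddG_exchange`, so no analytic correction is needed.

The enthalpic part of the RLF component is assembled from the mean total
potential energies of the first and last window of each constraint leg with
the same arithmetic as the free energies; `−TΔS = ΔG − ΔH` is then an exact
identity (`decompose_thermo()`). The non-interacting anchored toy
(`build_toy_oracle()`) shows the mechanism in its cleanest limit: by
equipartition the mean harmonic energy is (3/2)k_BT per atom *independent of
k_f*, so ΔH = 0 and the whole morph free energy (3/2)k_BT·ln(k_f1/k_f0) is
entropy — the acceptance suite verifies this against the closed form and
against numerical quadrature of the configuration integral.

## 3. The engine

Energies and forces are evaluated in C++ (Rcpp):

* Nonbonded: 12-6 Lennard-Jones (Lorentz–Berthelot combination) plus
  Coulomb (332.0637 kcal·Å/(mol·e²)), both multiplied by the standard C¹
  polynomial switch between 10 and 12 Å and exactly zero beyond the cutoff.
  The droplet is far smaller than the cutoff, so the switch is rarely
  active; it is retained so the pair model is well defined everywhere.
* Alchemically scaled (appearing/disappearing) pairs use the
  shifted-distance softcore `r² → r² + shift·(1 − s)·σ²` (shift
  coefficient 1) with the overall prefactor s, for *both* the
  Lennard-Jones and the Coulomb term. Softening the Coulomb distance too is
  a deliberate choice: a bare −q/r on a ghost atom with a bounded soft core
  undergoes a fusion catastrophe at intermediate λ. At s = 1 the pair is
  exactly the plain switched interaction.
* Ion morphs interpolate the ion's ε and σ linearly in λ instead of using
  softcore: both endpoints keep a full repulsive core, so there is no
  endpoint singularity to remove, and the unscaled ion–oxygen charges make a
  softcore treatment actively dangerous (see above).
* Bonded terms are harmonic with the 0.5·k·Δ² convention throughout (bond k
  in kcal/mol/Å², angle k in kcal/mol/rad², values transcribed from an
  additive all-atom protein force field). Intra-ligand nonbonded pairs are
  excluded; the two ligand sets of a dual-topology system never interact
  with each other.
* Dynamics: BAOAB-discretised Langevin at 310 K, 1 fs timestep, friction
  5 ps⁻¹, platform-independent Gaussian stream (mt19937_64 + Box–Muller), so
  a seed fixes the trajectory bit-for-bit. The ion never moves. Hydrogens
  are not constrained; masses are standard atomic masses.
* Minimisation: adaptive-step steepest descent with monotone energy.

One numerical caveat is documented rather than hidden: at 1 fs the stiffest
intramolecular modes (C–H stretches, ~11 fs period) are integrated near the
accuracy edge of BAOAB, which biases the *kinetic* temperature of those
modes upward by a few percent and the configurational variance of stiff
coordinates by a comparable factor. The bias is identical for the two ions
of a pair and largely cancels from the free-energy differences; thermostat
calibration tests therefore use softly anchored atoms (k_f ≤ 100), where the
bias is far below the statistical noise.

## 4. Estimators, schedules, errors

Each leg simulates every λ of its schedule once, in traversal order, chaining
the final configuration of one window into the next, with one window length
of pre-equilibration and the first 10% of each window discarded. Saved frames
are re-evaluated at the neighbouring λ values, giving, per window, the
forward and reverse perturbation energies.

* **EXP** (exponential averaging) per window, summed along the traversal; a
  reverse leg estimates the negated total, and `|ΔG_fw + ΔG_rv|` is the
  hysteresis diagnostic.
* **BAR** (Bennett acceptance ratio) per adjacent window pair, solved by
  root-finding on the standard self-consistency; it uses the forward work
  from the lower window and the reverse work from the upper window, so a
  single traversal supports it without extra sampling. BAR is the default
  leg total (lower variance); EXP forward/reverse is retained as the
  convergence diagnostic, and the two are cross-checked against each other
  and against closed forms in the tests.
* Standard errors are block averages (10 contiguous blocks per window,
  summed in quadrature across windows). Blocks of several picoseconds are
  long compared to the observed energy autocorrelation in these small
  droplets.

Restraint morphs use a λ schedule dense at both endpoints
(`{0, 10⁻⁵, 10⁻⁴, 10⁻³, 10⁻², 0.05 … 0.95, 0.99, 0.999, 0.9999, 0.99999, 1}`,
29 states), because whole ligand sets appear and disappear there; ion morphs
use 21 uniform windows. The default per-window sampling is 4 ns scaled by a
`scale` factor: `scripts/acceptance.R` runs at scale 0.05 (200 ps/window),
the test suite at 40 ps/window. The statistic being tested — the sign or a
threshold on a mean free-energy difference — does not depend on the
sampling length, only its standard error does; the campaign functions
report per-leg standard errors and (when both directions are run)
hysteresis so that the convergence of any given run is visible rather than
assumed.

## 5. Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| wall radius | 3.5 | Å | flat-bottom confinement of coordinating oxygens |
| k_wall | 100 | kcal/mol/Å² | "very large" one-sided wall stiffness |
| k_f grid | 0, 10^(−1..3) by half-decades | kcal/mol/Å² | fluctuation dial; the selectivity change saturates near the top |
| temperature | 310 | K | all sampling |
| timestep | 1 | fs | BAOAB Langevin |
| friction | 5 | ps⁻¹ | robust canonical sampling for stiff restraints |
| cutoff / switch | 12 / 10 | Å | nonbonded truncation |
| softcore shift | 1 | — | van der Waals radius shift coefficient |
| scale | 0.05 | — | per-window sampling, 1.0 = 4 ns |

Ion Lennard-Jones parameters and the hydration free energies are the
Joung–Cheatham monovalent-ion models (TIP3P-compatible set); both ship as
plain-text tables under `inst/extdata/` and are never hard-coded.

## 6. What the generators emulate — and what they do not

The synthetic-data layer produces four kinds of systems: abstract cages
(`build_abstract_system()`), transporter-site models (`build_site_model()`),
strained-cavity variants, and analytic-oracle toys (`build_toy_oracle()`).
They emulate the *composition and electrostatic character* of real ion
binding sites — dipolar coordinating groups, controlled coordination number,
damped positional fluctuations — in vacuo, with no water, no protein
scaffold, no polarisability and no periodic boundaries. Anchor positions for
abstract cages are the as-built ideal geometries (oxygens exactly at the
polyhedron/packing vertices at `R_opt`, carbons radially outward); for site
models they are per-ion energy-minimised coordinates. The transporter-site
starting coordinates are a packaged *synthetic idealised fixture* — ligands
placed at chemically sensible distances on packing-optimal directions and
then minimised — not a crystal-structure extraction; the file says so in its
header. Passing tests therefore demonstrate the mechanism in these model
systems, not quantitative selectivities of the real transporters.

The n = 5 and 7 anchor directions come from a seeded Riesz-energy packing
optimisation whose n = 4 and 6 solutions are checked against the exact
tetrahedron and octahedron; n = 8 uses the square antiprism (the 8-point
packing optimum) by default, with the cube available behind a flag.

## 7. Occupancy volumes and fluctuation maps

`occupancy_volume()` voxelises the union of atomic van der Waals spheres
over a trajectory at 0.1 Å resolution. The default mode is *cumulative* — a
voxel counts once it has ever been occupied — which measures the
configurational volume swept by the selection over the run and grows toward
the volume argument of the entropy mechanism; volumes of several thousand Å³
for a freely fluctuating cage are only reachable in this mode, since any
single frame's union of spheres is geometrically far smaller. A
VolMap-style *frame-fraction* mode (voxel counts if occupied in at least
`isovalue` of frames) is retained. Because cumulative volumes grow with
trajectory length, only matched-length comparisons are meaningful; the
package's own test compares the free-minus-frozen volume drop across ions at
matched sampling, where the ordering K⁺ > Na⁺ > Li⁺ expresses the mechanism.
`rms_fluctuation()` supplies the complementary per-atom picture and the
pooled RMSF that maps k_f onto an observable fluctuation scale.

## 8. Degenerate inputs, tie-breaks, guards

* `k_f = 0` restraint morphs return an exactly-zero leg (identical
  endpoints), not a simulation.
* Identity ion morphs and empty-site morphs return exactly zero.
* Anchors built for a different ion raise a strain-contamination error
  unless strain mode is requested explicitly; ion morphs refuse anchored
  systems.
* Construction rejects interacting atoms closer than 0.5 Å; dynamics aborts,
  naming the step, if |E| exceeds 10⁶ kcal/mol or goes non-finite.
* RDF first peaks are the first smoothed (3-bin) local maximum above
  g(r) = 1, falling back to the global maximum; ties inside the smoothing
  window resolve to the unsmoothed maximum.
* BAR falls back to EXP if the self-consistency equation has no bracketed
  root (degenerate all-one-sided data).

## 9. Known limitations

* The force-field fragments are transcriptions, not a bit-parity copy of
  any published engine's parameter files; absolute leg free energies are
  model-specific, and conclusions should rest on the differences the cycle
  is built from.
* The 8-ligand Na⁺/K⁺ cage sits near a sub-kcal/mol balance between the
  entropic confinement difference and the packing enthalpy of forcing all
  eight ligands to one radius around the smaller ion. Its net direction is
  sensitive to the fragment parameterisation and to the choice of 8-vertex
  geometry (square antiprism vs cube) — the package's campaigns resolve the
  n ≤ 7 and Li/Na shifts with clear margins, but the n = 8 shift should be
  treated as unresolved at this model fidelity.
* Entropy is obtained only as ΔG − ΔH from endpoint energies; no
  quasi-harmonic or normal-mode estimate is attempted.
* Desk-scale sampling (tens to hundreds of picoseconds per window) leaves
  per-cycle standard errors of a few tenths of a kcal/mol; the full 4 ns
  protocol (`scale = 1`) reduces them accordingly at proportional cost.
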