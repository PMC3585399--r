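# rlfep

Entropic ion selectivity from reduced ligand fluctuations: a desk-scale
molecular-mechanics and alchemical free-energy toolkit in R.

## The scientific problem

Ion channels and transporters discriminate between chemically near-identical
cations — Li⁺, Na⁺ and K⁺ differ only in radius — and several "cavity"
mechanisms have been proposed to explain how the positions of the
ion-coordinating ligands create that selectivity. A *rigid* cavity holds the
ligands at one fixed geometry; a *strained* cavity lets them adjust to a new
ion at an energetic cost. This package studies a third mechanism, **reduced
ligand fluctuations (RLF)**: the ligands are free to sit at their *optimal*
distance for every ion (no strain at all), and only the *amplitude of their
thermal motion* is restricted. Restricting motion costs more entropy around a
large ion than a small one — the configurational volume available to ligands
at a larger coordination radius is larger — so damping fluctuations alone
drives selectivity toward the smaller ion.

The package is aimed at computational biophysicists who want a transparent,
fully scriptable implementation of this thought experiment: a bespoke small
molecular-mechanics engine (switched 12-6 Lennard-Jones + Coulomb, harmonic
bonded terms, flat-bottom spherical wall, per-atom harmonic anchors, BAOAB
Langevin dynamics at 310 K with 1 fs steps), dual-topology free energy
perturbation (FEP), and the thermodynamic-cycle bookkeeping that turns leg
free energies into exchange selectivities.

## Model and cycle

A model binding site is one fixed cation plus *n* small dipolar ligands
(formaldehyde-like: C +0.5 e, O −0.5 e, H 0; or carbonyl / hydroxyl /
carboxylate fragments for the transporter-site models). Every coordinating
oxygen is confined to a 3.5 Å sphere by a one-sided harmonic wall. Thermal
fluctuations are reduced by anchoring every ligand atom in a harmonic
potential ½·k_f·|r − r₀|², with anchors placed at each ion's **own** optimal
coordination geometry — the first peak of the unconstrained ion–oxygen radial
distribution function, `R_opt` — so that no strain is introduced.

For an ion pair (A, B) the exchange free energy is assembled from four legs:

```
ddG_exchange(A, B) = dG_out(B) + dG_site(B→A) − ddG_hydr(B→A) − dG_out(A)
```

where `dG_out(M)` is the dual-topology restraint morph (anchored ligand set
annihilated while a free, wall-only set is exnihilated; both endpoints are n
ligands coordinating M), `dG_site(B→A)` is the ion morph in the fluctuating
site, and `ddG_hydr` is the bulk-water leg taken from tabulated hydration
free energies of the ion models. Positive values mean B is preferred in the
site. The RLF component is the k_f-dependent part,

```
ddG_RLF(k_f) = ddG_exchange(k_f) − ddG_exchange(0) = dG_out(B) − dG_out(A),
```

identically zero at k_f = 0. Per-window free energies come from exponential
averaging (EXP) and the Bennett acceptance ratio (BAR); forward/reverse
hysteresis is the convergence diagnostic. The enthalpic part is extracted
from endpoint mean potential energies and `−TΔS = ΔG − ΔH` closes the
decomposition exactly.

## Worked example

A two-minute analytic check — tightening a single anchored atom from
k_f = 1 to 10 kcal/mol/Å², whose free energy is (3/2)k_BT·ln 10 in closed
form:

```r
library(rlfep)
sys <- build_toy_oracle(1, kf = 1, kf_target = 10)
sam <- collect_fep_samples(sys, lambda_schedule("uniform", 11), 20000, seed = 7)
estimate_bar(sam)$total_dG        # 2.131  (closed form: 2.128 kcal/mol)
```

A real Na⁺/K⁺ campaign for the octahedral 6-ligand cage (about four minutes
at 50 ps per window):

```r
ra <- find_r_opt("Na", 6, nsteps = 50000, seed = 1)   # r_opt = 2.325 A
rk <- find_r_opt("K",  6, nsteps = 50000, seed = 1)   # r_opt = 2.675 A
legNa <- run_restraint_morph("Na", 6, 1000, cage_anchors("Na", 6, ra$r_opt),
                             seed = 5, nsteps_per_window = 50000)
legK  <- run_restraint_morph("K",  6, 1000, cage_anchors("K", 6, rk$r_opt),
                             seed = 6, nsteps_per_window = 50000)
site  <- run_ion_morph(6, "K", "Na", seed = 9, nsteps_per_window = 50000,
                       r_start = rk$r_opt)
assemble_cycle(legNa, legK, site)
#> Exchange cycle K -> Na (n = 6)  kf = 1000
#>   dG_constraint_A (Na) =   26.516
#>   dG_constraint_B (K)  =   22.577
#>   dG_site_exchange     =  -15.618
#>   ddG_hydr             =  -16.700
#>   ddG_exchange         =   -2.858 +/- 0.163 kcal/mol (positive: K preferred)
#>   ddG_RLF              =   -3.940 kcal/mol
```

Read: at k_f = 0 the carbonyl cage inherently prefers K⁺ (ddG_exchange(0) =
dG_site − ddG_hydr = +1.1 kcal/mol); confining every ligand atom at its
own-ion optimal position (k_f = 1000) costs ~4 kcal/mol more around the
larger K⁺ than around Na⁺, flipping the site to Na⁺-selective — the RLF
mechanism. `decompose_thermo()` shows the shift is carried predominantly by
`−TΔS`. The same pipeline runs the LeuT/Glt_Ph site models
(`build_site_model()`, `rlf_curve(pair, site = ...)`).

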