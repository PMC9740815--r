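---
title: "Models and methods behind hapthermal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hapthermal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapthermal)
```

## The scientific problem

Hydroxyapatite (HAP), Ca₁₀(PO₄)₆(OH)₂, stacks its hydroxyl ions in
channels along the hexagonal *c* axis. On heating, OH⁻ ions detach from
these channels and leave the crystal (dehydroxylation), and at still
higher temperatures the lattice itself decomposes. `hapthermal`
implements a classical molecular-dynamics (MD) pipeline for this
process: construct the crystal from its tabulated lattice parameters,
thermostat it at controlled temperatures, count the hydroxyls that
escape, detect melting, and convert removal energies into equivalent
temperatures with an explicit uncertainty model.

## Crystal model

The hexagonal P6₃ unit cell (a = b = 9.417 Å, c = 6.875 Å, γ = 120°)
holds 44 atoms: 10 Ca, 6 phosphate groups, and 2 hydroxyls in the OH
channel. The fractional coordinates of the basis are **configuration**,
not code: they ship in `inst/extdata/hap_p63_basis.yaml`, assembled from
the standard P6₃/m single-crystal refinement with the half-occupied
hydroxyl site resolved to the ordered P6₃ arrangement (both OH parallel
to +c; `oh_orientation: disordered` flips each hydroxyl with probability
1/2 under a seed). Validation enforces the three structural invariants —
44 basis atoms, exactly two O–H hydroxyl pairs, fractional coordinates
in [0, 1) — and bond detection pairs each P with its four nearest
oxygens and each hydroxyl H with its O, unwrapping bonded partners to
the nearest image so that replication keeps molecular groups whole.

`replicate_cell()` tiles the cell explicitly (no symmetry-operation
engine); 4×4×2 replication gives the 1408-atom, 64-hydroxyl supercell
used as the main model. `solvate()` surrounds a cluster with a shell of
rigid-geometry 3-site waters placed by rejection sampling
(`n_waters = "auto"` fills the shell volume at 0.997 g/cm³; a fixed
count reproduces a specific model such as the 1504-water shell), and
`expand_box()` adds vacuum headspace so escaping ions and vapour have
somewhere to go. `expand_box()` does exact margin arithmetic: each cell
vector is lengthened by exactly the requested amount, and two expansions
compose additively.

## Interaction model

The force field is deliberately config-driven
(`inst/extdata/hap_ff.yaml`): point-charge Coulomb
(k_C = 332.0637 kcal·Å/(mol·e²)), Lennard-Jones pair terms in either the
12-6 form 4ε[(σ/r)¹²−(σ/r)⁶] or the class-II 9-6 form
ε[2(r₀/r)⁹−3(r₀/r)⁶] (minimum −ε at r₀ — the convention we adopt for
"9-6"; the choice of which pairs use it is a config decision, defaulting
to Ca–O), harmonic bonds k(r−r₀)² and angles k(θ−θ₀)². Unspecified pairs
are completed by Lorentz–Berthelot mixing; explicit entries override.
Nonbonded sums run under the minimum-image convention with a plain
cutoff (default 10 Å) and an energy shift to zero at the cutoff — a
documented deviation from production-grade Ewald electrostatics, chosen
for desk-scale transparency. Bonded 1-2 and 1-3 pairs are excluded.

The shipped parameter values are a self-consistent default set — formal
ionic charges partitioned over the phosphate (P +1.4, O −1.1) and
hydroxyl (O −1.425, H +0.425) groups with Ca +2, conventional LJ radii —
standing in for fitted mineral force fields, which are not freely
redistributable. Every quantitative result that depends on these values
is to be read qualitatively, and none of the package's acceptance-level
checks depends on them.

Units are fixed throughout: kcal/mol, Å, ps, amu, elementary charge;
k_B = 8.6173·10⁻⁵ eV/K and 1 kcal/mol = 0.0433641 eV for conversions.

## Dynamics and the collisional thermostat

Integration is velocity-Verlet. Temperature control follows the
collisional (stochastic-collision) picture: the surrounding medium is
modelled as virtual point particles with Maxwell-distributed velocities
at the setpoint T_Ref; at random times a virtual particle elastically
collides with a system atom, changing its velocity by

Δv = 2m₀/(m₀+m) (v₀ − v),

which conserves two-body energy and momentum. The Poisson stream of
collisions is realised per atom and per step as
Bernoulli(collision_rate · dt). Thermostat parameters that have no
single canonical value are exposed with defaults chosen once:

| parameter | default | why |
|---|---|---|
| `collision_rate` | 10 ps⁻¹ per atom | fast equilibration while leaving vibrational dynamics recognisable |
| `m0` | mass of the struck atom | makes each collision a full velocity exchange — the fastest-equilibrating and most common choice |
| `dt` | 0.5 fs | resolves the stiff O–H stretch (~10 fs period) |
| `sample_interval` | 1 ps | the frame spacing the detachment analysis assumes |

Waters are **flexible** (stiff harmonic bonds and angle), not rigidly
constrained; with the 0.5 fs step this is stable and avoids a constraint
solver that nothing downstream needs. Kinetic temperature is the
equipartition readout T = Σmᵢvᵢ²/(N_dof·k_B) with N_dof = 3N by default.
With the thermostat off (`collision_rate = 0`) the integrator is plain
NVE; energy-conservation tests use dt = 0.25 fs, where the max–min
total-energy excursion over 10⁴ steps on the toy crystal is below 10⁻⁴
relative (0.5 fs gives ~3·10⁻⁴ — the stiff bond dominates the shadow-
Hamiltonian error).

Both protocols are first-class: `run_nvt()` for relaxation at
fixed setpoints (the default grid is 800–1175 K in 25 K steps, 16
points) and `run_linear_heating()` for T_Ref = T₀ + rate·t (700 K +
0.1 K/ps over 7 ns reaches 1400 K). `run_protocol()` orchestrates 16
(or any number of) replicates seeded `master_seed + i`, writes per-
replicate extended-XYZ trajectories and detachment CSVs, aggregates a
JSON report, and resumes per replicate.

## Detachment counting

At each frame the minimum distance from every tagged OH ion to the host
is computed and compared with the 5 Å threshold; a per-ion binary vector
V flips permanently to 1 on first crossing, so Σ V is the number of ions
that have *ever* detached — an ion that returns stays counted. Two
choices the distance rule leaves open are resolved as explicit flags
with these defaults: the ion's distance is the minimum over **both** its
atoms (O and H) — the most conservative reading — and the host set is
all crystal atoms **including other hydroxyls but excluding water**
(water is not part of the crystal). Distances use the frame's box under
the minimum-image convention.

Onset detection on a mean detachment-vs-temperature curve is this
package's own rule: slide a 50 K window along
the linearly interpolated curve and report the end of the first window
whose secant slope exceeds 0.02 ions/K; both numbers are arguments.
Melting is flagged from the radius of gyration
Rg = √(Σmᵢ|rᵢ−r_com|²/Σmᵢ): a sustained drop of at least
`drop_fraction` below the initial plateau (first 10 frames, 5
consecutive sub-threshold frames by default) marks globulation collapse.

## Removal-energy profile and error model

`removal_profile()` rigidly translates the selected hydroxyl(s) along
the *c* direction and records single-point energies of the frozen
system at each displacement z — no relaxation, so the scan is
deterministic; a relaxation hook is deliberately absent. The profile's plateau
(last 10% of the grid, flat to 1% of the provisional |ΔE|) minus the
bound-state energy gives |ΔE|; `per_cell()` divides by the cell count
and converts to eV; T = |ΔE₁|/k_B gives the equivalent temperature. For
scans the cluster should be open-boundary (non-periodic): under periodic
wrapping a displaced ion never actually leaves.

The uncertainty model has two layers. First, the thermostat's own
temperature spread obeys 2σ² = T_Ref, i.e. σ = √(T_Ref/2), implemented
verbatim in the dimensionally informal convention in which both sides
carry kelvin: σ(1000 K) ≈ 22.36 K, σ(1150 K) ≈ 23.98 K, a 2σ band of
±48 K at 1150 K; wider kσ bands are always k times σ, computed from the
formula. Second,
coordinates are smeared by quantum/thermal uncertainty
Δz = ħ/√(2mk_BT) ≈ 0.155 Å for hydrogen at 1000 K; the energy error of
the scan is the largest profile change over that Δz within the
near-surface window (first 2 Å by default), treated as a symmetric
spread ±error/2, so the relative error is δ = (error/2)/|ΔE| — about
0.097 for a 10.73 kcal/mol near-surface spread against |ΔE| ≈ 55.21
kcal/mol. The whole chain is evaluated without intermediate rounding.

## Synthetic fixtures and what tests can (and cannot) show

All tests run on generated inputs:

- `make_toy_crystal()` — a finite binary ionic lattice (±0.35 e,
  simple-cubic cells, 3.2 Å constant, open boundaries) with OH-like
  charged diatomics replacing anion sites spread across the lattice.
  Charge and LJ magnitudes are scaled so a diatomic's removal energy is
  O(10–100) kcal/mol (measured ≈ 50 kcal/mol for the single-diatomic
  default), mimicking the *shape* of a hydroxyl removal profile without
  claiming mineral realism.
- `make_scripted_trajectory()` — trajectories whose detachment events
  happen at known frames: each scripted ion is displaced along its own
  axis until its measured minimum host distance equals the scripted
  target, and the construction self-verifies by re-measuring.
- `make_velocity_ensemble()` — Maxwell velocities at a stated
  temperature; `make_melting_rg_series()` — plateau-plus-sigmoidal-
  collapse Rg series with noise.

The temperature triple used in the detachment-dominance test
(600/1000/1600 K, 8 seeds, 8 ps) was chosen once so that k_BT spans
from well below to comparable with the toy diatomic's effective binding,
putting the evaporation transition on picosecond timescales; at those
settings the mean counts rise ≈ 0.1 → 1.3 → 1.5.

What passing tests establish: the integrator conserves energy and
momentum; the thermostat drives the kinetic temperature to the setpoint
with Maxwellian velocities; the detachment ledger exactly equals a
brute-force historical-OR oracle and is monotone; removal profiles
match an independent pair-sum oracle to 10⁻⁸; all closed-form
conversions reproduce their closed-form values. What they do **not**
establish: that real HAP dehydroxylates at ~1150 K under this code —
that statement lives at full scale (16 replicates × 10 ns on
the solvated 5920-atom system with the original, unpublished force-
field parameters), which the functions support but the shipped tests do
not run. The headline onset temperature, the ~10 ions detached at
1150 K, and melting at ≥1500 K are therefore represented here by the
scaled-down property checks above, not reproduced numerically.

## Numerical choices and degenerate inputs

- Hexagonal cells are handled as general triclinic boxes; minimum image
  uses fractional-coordinate rounding (exact for orthorhombic boxes and
  for distances well under half the box, the regime all analyses use).
  A finite cutoff must be smaller than half the smallest perpendicular
  box width, enforced at evaluation time.
- Overlap tolerance at construction defaults to 1.2 Å (below the
  shortest covalent bond treated as an exception, O–H ≈ 0.96 Å);
  validation brute-force scans systems up to 2000 atoms.
- Water placement rejects candidates within 2.0 Å of anything and fails
  loudly, reporting the achieved count, after bounded retries.
- Integration aborts with the step index if any coordinate exceeds
  10⁶ Å or turns non-finite.
- `total_change()` errors (advising a longer grid) when the profile's
  tail is not flat; a constant profile returns 0. The onset detector
  returns an `NA` sentinel on flat series; `melting_flag()` errors on
  series shorter than its plateau-plus-sustain window.
- All stochastic stages (solvation, thermostat, fixtures) consume an
  explicit seed and are bit-reproducible; RNG state of the calling
  session is saved and restored.

## Known limitations

Plain cutoff electrostatics instead of Ewald; flexible rather than
rigidly constrained water; no NPT barostat (box sizes are inputs); no
proton hopping or hydrogen-bond analysis; the shipped force-field
parameters are a documented stand-in rather than a fitted mineral force
field; desk-scale tests cannot validate full-scale transition
temperatures. The PDB writer stores group tags in the segment field and
ion ids in residue numbers, which round-trips through this package but
is a convention other tools will ignore.
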