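---
title: "Modeling chromosome compaction by crowders and a bridging protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromosome compaction by crowders and a bridging protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`nucleohns` simulates a coarse-grained model of a bacterial nucleoid: a
circular chromosome represented as a ring of `N` spherical monomers, the
nucleoid-structuring protein H-NS represented as mobile patchy dimers, and
the cytoplasm's macromolecules represented as inert spherical crowders, all
in a cubic box with periodic boundary conditions. The model probes two
compaction mechanisms and their interplay: *bridging* (a dimer binding two
genomically distant sites) and *depletion* (entropic attraction between
chain segments induced by crowders), which experiment and theory suggest
act synergistically.

Reduced units are used throughout: the monomer diameter `sigma`
(2.5 nm, about 7.35 bp of hydrated B-DNA) is the length unit, the thermal
energy `epsilon = kT` the energy unit, and `tau = sigma*sqrt(m/epsilon)`
the time unit with all masses set to 1 (mass does not affect equilibrium
observables, which are the package's entire scope).

### Nonbonded interactions

Every pair of species interacts through a truncated-shifted Lennard-Jones
potential

  U(r) = U_LJ(r) - U_LJ(r_c)  for r < r_c,  0 otherwise,
  U_LJ(r) = 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ],

indexed by species 1 = monomer, 2 = patch, 3 = core, 4 = crowder. All
pairs are purely repulsive (WCA: cutoff at the minimum `2^(1/6) sig_ij`)
except patch-monomer, whose cutoff is extended by `0.085 sigma` past the
minimum so that it is attractive for `0.6 < r < 0.685`. Its strength
`eps_12 = 29` makes the well depth about `-8.65 kT`, chosen to match the
measured H-NS-DNA binding free energy (about -21 kJ/mol); at this strength
roughly a third of the dimers are bound in the crowder-free reference
state, which is the package's key stochastic acceptance point. Patch-core
and patch-crowder pairs do not interact at all; they are represented as
explicitly *inactive* entries rather than zero-strength ones, so
`dump_table()` exposes the full parameter set entry by entry for audit.

A note on significant digits: the interaction table stores the rounded
three-decimal values `sigma_12 = 0.535` and `sigma_22 = 0.178` rather
than the defining expressions `0.6/2^(1/6)` and `0.2/2^(1/6)`. The
difference is invisible everywhere except the patch-monomer well depth,
where the three-decimal value gives the calibrated `-8.65 kT` while the
analytic expression gives -8.72; the package standardizes on the rounded
values, which the calibration target singles out.

### Bonded interactions

Consecutive ring monomers are joined by FENE springs,
`U = -(k0 r0^2 / 2) ln[1 - (r/r0)^2]` with `k0 = 30 eps/sigma^2` and
`r0 = 1.5 sigma`; combined with the WCA monomer repulsion this is the
standard bead-spring (Kremer-Grest) construction that prevents chain
crossing, with an equilibrium bond length near `0.97 sigma`. Bonded
neighbours also feel the 1-1 WCA term, as in that convention.

Each H-NS dimer is a triplex: a core sphere of diameter `sigma` with two
patch spheres embedded at its poles, `0.4 sigma` from the centre. The
internal energy applies one radial harmonic term
`K (|r_patch - r_core| - 0.4)^2` per patch (`K = 120 eps/sigma^2`) plus a
single shared angle term `k_b (theta - pi)^2` (`k_b = 50 eps`) on the
angle between the two core-to-patch vectors, keeping the patches
antipodal. This geometry deliberately suppresses the "U-shaped" *cis*
configuration in which both patches reach nearby sites; the patch
placement also prevents one patch from wrapping multiple monomers. The
symbol `theta` is used both for this internal angle and, everywhere else,
for the binding probability; the two never meet in code (one lives in the
bonded parameters, the other in the observables).

## Dynamics

The equations of motion are integrated with velocity-Verlet at
`dt = 0.005 tau` under a Langevin thermostat at `T = 1` with damping time
`1 tau`. The thermostat discretization is the impulse-style one common to
MD engines: at every force evaluation each degree of freedom receives a
friction force `-(m/tau_d) v` and a Gaussian random force of variance
`2 m kT / (tau_d dt)`. Equilibrium observables are insensitive to this
choice, which is why the test suite checks them (equipartition to 2%,
NVE energy conservation with the thermostat off) rather than any
particular discretization artifact. The friction applies to every
particle, including patches and crowders.

Forces come from a Verlet neighbour list with per-pair-type list cutoffs
(`r_c,ij` + skin, default skin 0.7 sigma), rebuilt whenever any particle
has moved more than half the skin; the list build is either an exact
all-pairs sweep or a cell-list search, and the test suite asserts the two
produce bit-identical forces. The compiled kernels use a seeded
xoshiro256++ generator with a ziggurat normal sampler for the thermostat,
so trajectories are bit-reproducible for a given seed on a given
platform. A FENE bond stretched to its divergence length or a non-finite
coordinate aborts the run with the offending bond or step in the error
message, as these indicate an unstable integration rather than physics.

## System construction

`assemble_system()` builds a deterministic (seeded) initial state:

* **Ring**: monomers start on a closed planar circle whose neighbour
  chord equals the FENE+WCA equilibrium bond length. When the circle does
  not fit the box (the production geometry: a ring of circumference
  ~194 sigma in a 50-sigma box), the ring is instead wound `p` times
  around a torus — still a closed, knot-free, non-self-intersecting
  curve, with winding-winding clearance checked explicitly. Equilibration
  erases the initial shape; the stationarity test verifies this.
* **H-NS**: inserted at uniformly random positions and orientations with
  overlap rejection.
* **Crowders**: placed on a jittered cubic lattice from which sites too
  close to the polymer or cores have been removed. Rejection sampling,
  the obvious alternative, is quadratic in particle number and becomes
  infeasible near the densest supported fraction (9,549 crowders at
  phi_c = 0.32); the lattice start is gap-respecting by construction at
  any supported density, and the order it introduces decays within a few
  tau. When anything was inserted under a relaxed criterion (or dimers
  were moved to their anchor sites), a capped steepest-descent push-off
  restores a minimum clearance of `0.85 sigma_ij` for every active pair
  before dynamics start.
* **Velocities**: Maxwell-Boltzmann at the target temperature, with the
  centre-of-mass drift removed.

The crowder count realizes the requested volume fraction as
`round(phi_c L^3 / (pi sigma_c^3 / 6))` — nearest-integer rounding keeps
the realized fraction unbiased within half a particle volume.

Two control variants isolate the synergy mechanisms:
`hns_permeable_to_crowders` zeroes the core-crowder interaction (dimers
then feel no depletion force, isolating that contribution), and
`n_anchored` tethers a chosen number of dimers to random distinct
monomers by a stiff harmonic bond (rest length 0.6 sigma, k = 120) on one
patch — anchoring by a bond rather than by freezing coordinates leaves
the dimer free to rotate and bridge, which is the point of the control.

## Observables

* **Compaction**: the ring's radius of gyration, computed after
  unwrapping the ring by walking its bonds under the minimum image
  convention; the walk must close, and a bond longer than half the box is
  reported as a broken ring rather than silently misunwrapped. The
  compaction ratio divides by `Rg0`, *measured* from a matched run with
  no crowders and no binders — never assumed.
* **Binding**: a patch is in contact with a monomer when their
  minimum-image distance is below `0.685 sigma`. This cutoff is the outer
  edge of the attractive patch-monomer well, the natural definition of
  "bound" for this potential; it is exposed as a parameter. A dimer with
  one patch in contact is dangling, with both bridging; the binding
  probability `theta` is the bound fraction, and the dangling/bridging
  fractions sum to it exactly (count arithmetic). For bridging dimers the
  genomic span is the minimal ring distance between the closest pair of
  bound monomers across the two patches; spans of more than two monomers
  are labelled *trans*, the threshold again exposed as a parameter.
* **Clustering**: dimers whose cores are within `3 sigma` are connected;
  clusters are connected components of that graph (via igraph), shape
  agnostic, including unbound dimers. The headline "mean cluster size"
  is the number average pooled over frames (total dimers over total
  cluster count); a mass-weighted average would emphasize the large
  cluster that forms at high crowding and is easy to compute from the
  reported histogram if wanted.
* **Errors**: time means carry moving-block bootstrap standard errors
  (20 blocks, 200 resamples, fixed internal seed), since successive
  frames are strongly correlated.

## Problem sizes used by the tests and the acceptance script

The production protocol (1e8 equilibration steps, 1e9 production steps,
sampling every 5e3) is available as a preset but is a cluster-scale
campaign. The package's own checks run reduced schedules chosen so that
the statistical error is several times smaller than the tolerance being
checked:

* Crowder-free reference point (N = 200, 30 dimers, 290 particles):
  2e4 tau equilibration, 4e4 tau production per replica, three replicas
  plus a matched binder-free baseline (6e4 tau of production in the test
  suite, since the baseline enters every compaction ratio). With these
  spans the replica-level standard errors are ~0.01 on `theta` and ~2%
  on `Rg`, against tolerances of 0.05. A two-sided check — starting the
  same system from a compacted ring instead of the swollen initial curve
  — reproduces the same production mean, so the reduced-schedule value
  is converged rather than history-dependent.
* Qualitative synergy (N = 50, 8 dimers, phi_c up to 0.2 in a 20-sigma
  box): 2.5e3 tau equilibration, 6e3 tau production per condition — the
  direction of the crowding response, not its magnitude, is the claim
  checked there.
* The Gaussian-ring scaling check adapts its span to the slowest Rouse
  mode of each chain length (several relaxation times of production).

The full-scale curves (for example the compaction ratio 0.54 at
phi_c = 0.32, or the second histogram peak near cluster size 24) require
the production campaign and are deliberately not asserted at desk scale;
the synergy test checks their direction on a small system instead.

## What the generator does and does not emulate

The builder-plus-simulator produces equilibrium ensembles of the model —
which is itself a deliberate idealization. Passing tests show the
Hamiltonian, thermostat and estimators are implemented correctly and
reproduce the model's calibrated reference behaviour; they do not show
that real nucleoids behave this way. In particular the model has no
electrostatics (so no Mg2+-dependent switching of H-NS between coating
and bridging), no DNA bending stiffness or supercoiling, no sequence
specificity, no cis binding geometry, monodisperse crowders, and no
hydrodynamics; binding/unbinding kinetics are outside scope because only
equilibrium quantities are collected.

## Numerical choices and degenerate inputs

* Angle forces use the standard `1/sin(theta)` formulation with a
  `1e-8` floor; at the rest geometry (`theta = pi`) the force limit is
  finite and the floor is inert.
* The truncated-shifted potential has a force discontinuity at the
  patch-monomer cutoff (a property of the model, not a bug); NVE drift
  checks therefore run at `dt = 0.001`.
* `potential_minimum()` distinguishes attractive pairs (interior
  minimum, found by golden-section refinement) from WCA pairs (minimum
  exactly zero at the cutoff).
* Inactive pairs return exactly 0 energy and force by contract; calling
  the binding classifier on a system with no dimers is an explicit error
  ("theta undefined") rather than NaN.
* `n_hns = 0` trajectories aggregate with NA binding and cluster columns,
  so baselines flow through the same pipeline.
* Crowder-free systems trim the neighbour-list cutoff to the species
  actually present, so the 290-particle reference system does not pay for
  the crowder-crowder interaction range.

## Limitations

Single-threaded; the N = 2000 geometry is supported by the builder and
presets but a full sweep at that size is a cluster campaign. Observables
assume the assembler's particle layout (monomers first in ring order,
then core/patch/patch triplets) — trajectories read from external files
must follow it. Bootstrap errors assume the block length exceeds the
correlation time, which holds for the schedules above but should be
rechecked for custom ones.
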