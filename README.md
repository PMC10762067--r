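# nucleohns

Coarse-grained Langevin-dynamics simulation and analysis of bacterial
chromosome compaction by two cooperating agents: the cross-linking
nucleoid-associated protein H-NS and inert macromolecular crowders.

The chromosome is a ring of `N` beads (bead diameter σ = 2.5 nm ≈ 7.35 bp)
joined by FENE springs; H-NS dimers are mobile "patchy" triplexes — a core
sphere with two sticky patches held antipodally by stiff bonds and an
angular potential — whose patches bind the polymer non-specifically;
crowders are plain spheres at volume fraction φc. All species interact by
truncated-shifted Lennard-Jones potentials; every pair is purely repulsive
(WCA) except patch–monomer, which is attractive in 0.6 < r < 0.685 σ with
ε₁₂ = 29 kT, giving a binding well of ≈ −8.65 kT, comparable to the
measured H-NS–DNA binding free energy. Dynamics are velocity-Verlet with a
Langevin thermostat (T = 1 ε/k_B, dt = 0.005 τ) in a periodic cubic box,
with compiled (Rcpp) force and integrator kernels.

The analysis pipeline computes the observables that quantify the
compaction story:

* **Rg / Rg0** — the ring's radius of gyration (unwrapped across periodic
  boundaries) relative to a measured crowder-free, binder-free baseline;
* **θ** — the fraction of bound dimers (a patch is bound within the
  0.685 σ attraction range), decomposed exactly into *dangling*
  (one-site) and *bridging* (two-site) fractions, with genomic bridge
  spans classified cis/trans;
* **H-NS cluster statistics** — connected components of cores within 3 σ:
  per-frame partitions, pooled size histograms and the mean cluster size.

Deterministic fixture generators (`make_fixture()`) produce frames with
analytically known observables so the whole analysis stack is testable
without running dynamics.

## Worked example

A 100-monomer ring with 12 dimers at φc = 0.2, against its own baseline
(about two minutes on one core):

```r
library(nucleohns)

spec <- system_spec(n_monomers = 100, box_side = 30, phi_c = 0.2,
                    n_hns = 12, seed = 1)
traj <- run_dynamics(spec, integrator_settings(seed = 1),
                     run_schedule_tau(2500, 5000, 25))

base <- system_spec(n_monomers = 100, box_side = 30, phi_c = 0,
                    n_hns = 0, seed = 1)
rg0 <- aggregate_observables(
  run_dynamics(base, integrator_settings(seed = 1),
               run_schedule_tau(2500, 5000, 25))
)$summary$mean_rg

aggregate_observables(traj, rg0 = rg0)
#> observable_summary over 200 frames
#>   <Rg> = 4.595 +/- 0.104 sigma
#>   <Rg>/Rg0 = 0.845 +/- 0.019 (Rg0 = 5.436)
#>   theta = 0.594 +/- 0.026 (dangling 0.101 + bridging 0.493)
#>   mean cluster size = 1.55
```

Read: crowding at φc = 0.2 compacts this ring by ~15% relative to the
bare baseline, most bound dimers are cross-linking rather than dangling,
and dimers have begun to cluster (mean cluster size 1.55; the pooled
histogram in the returned object shows clusters up to size ~6). Errors
are moving-block bootstrap standard errors of the time means.

Systems, interaction tables and schedules are all explicit objects:
`interaction_table()` carries the model's 4×4 pair-parameter table
(`dump_table()` prints it), `preset("N200")` / `preset("N2000")` carry
the two supported geometries and the sweep grid, and control variants
(H-NS permeable to crowders; dimers anchored to random sites) are flags
on `system_spec()`. A thin command-line front end lives in
`inst/cli/nucleohns.R` (`build`, `simulate`, `analyze`, `sweep`,
`fixtures`, `dump-table`).

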