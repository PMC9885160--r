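# amdenm

Adaptive molecular dynamics with excited normal modes (aMDeNM) on
coarse-grained bead models, with the landscape analyses used to map the
conformational space of a flexible protein tail.

## The problem

Small GTPases such as Ran carry a flexible C-terminal tail whose open
conformations matter biologically (partner binding) but are invisible to
both crystallography and plain molecular dynamics: an unbiased trajectory
finds a stabilizing contact on the globular domain and stays trapped
there. aMDeNM escapes this trap by repeatedly injecting a small amount of
kinetic energy along collective directions built from low-frequency normal
modes, adapting those directions as the structure moves away from the
starting point.

This package implements the full protocol at desk scale for anyone who
wants to study, test, or extend the algorithm itself:

- a **synthetic two-domain generator** — a compact quasi-ellipsoidal core of
  beads plus a flexible tail ending in an ideal helix, with a matching toy
  force field (bonds, angles, switched LJ + Coulomb) and known statistical
  fixtures, so every downstream stage has an oracle;
- **normal modes** from an anisotropic elastic network (pairwise springs
  \- \gamma \hat r \hat r^T within a cutoff) or from finite differences of the
  toy potential; mass-weighted diagonalization, thermal RMSF per mode
  (var_i = k_B T / \lambda_k \cdot |a_{k,i}|^2 / m_i), and mode selection by
  regional RMSF contribution;
- the **excitation engine**: random unit combinations of the selected
  modes, a sequential diversity filter (accept a direction only if the
  structures displaced 1.0 Å along it and along every accepted direction
  differ by > 1.15 Å RMSD), exact kinetic-energy injection of
  1.25 kcal/mol per 0.2 ps Langevin segment, and the adaptive update:
  when the system has moved ≥ 0.5 Å along the excitation direction *and*
  its effective displacement deviates by more than 60° from it, the
  direction is replaced by the (normalized) displacement from the segment
  anchor to the last segment's average position;
- the **landscape analyses**: RMSF/RMSD with Kabsch superposition, the
  anchor/inertia coordinate frame (origin at the tail-base residue,
  z along the domain's largest-inertia axis pointing away from the
  domain), tail-helix center-of-mass tracking, residue-pair nonbonded
  interaction-energy maps, and convex-hull coverage statistics.

Units: Å, ps, amu, kcal/mol; harmonic terms use the CHARMM convention
`k (b - b0)^2`; 1 kcal/mol = 418.4 amu Å²/ps²; k_B = 0.0019872041
kcal/mol/K; Coulomb constant 332.0636 kcal Å/(mol e²).

## Worked example

```r
library(amdenm)

sys   <- make_two_domain_system(synthetic_spec())     # 40-bead core + 12-bead tail
s     <- sys$structure
modes <- diagonalize_hessian(build_enm_hessian(s), s$atoms$mass)
modes
#> <mode_set> 156 modes (6 zero), lowest nonzero eigenvalue 5.179e-07 kcal/mol/A^2/amu

tail_sel <- select_atoms(s, "resid 41:52")
picked   <- select_modes(modes, tail_sel, 4)          # 4 modes moving the tail
picked
#> [1]  7  8  9 10

cfg  <- excitation_config(n_excitations = 20)         # defaults: 1.25 kcal/mol, 0.2 ps
camp <- run_campaign(sys$params, s, modes, picked, n_replicas = 3,
                     config = cfg, seed = 1)
camp
#> <campaign_result> 3 replicas, 60 conformations

dom <- select_atoms(s, "resid 1:40")
hel <- select_atoms(s, "resid 47:52")
track <- com_track(campaign_trajectory(camp), s, 41, dom, hel)
head(track, 3)
#>   frame        x          y        z
#> 1     1 1.406678 -0.9448286 22.98981
#> 2     2 1.773283 -1.2230431 23.07718
#> 3     3 2.280124 -1.3595423 23.42871

coverage_stats(track)$hull_area
#> [1] 125.5
```

Reading the output: each row of `track` is one sampled conformation's
tail-helix COM in the domain-anchored frame — z ≈ +23 Å says the helix
sits well away from the core (the extended start), and the x–y spread
(hull area ≈ 125 Å² after only 60 excitations) is the footprint of tail
orientations the campaign has visited; a plain Langevin run of the same
length typically covers an order of magnitude less (see the sampling
test in `tests/testthat/test-acceptance.R`). `interaction_map()` +
`top_contacts()` then show which core/tail residue pairs hold any closed
conformation together.

A command-line front end covering the same operations is installed at
`inst/cli/amdenm` (subcommands `graft`, `modes`, `excite`, `rmsf`,
`rmsd`, `comtrack`, `imap`).

## Scope

Desk-scale by design: bead-per-residue models, vacuum switched
electrostatics (no PME), no explicit solvent, no constraints, no
barostat, no all-atom force field. See `vignettes/amdenm-methods.Rmd`
for the model, parameter choices, numerical conventions, and known
limitations.
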