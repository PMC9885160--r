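---
title: "Methods: mode-excited sampling on a synthetic two-domain system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mode-excited sampling on a synthetic two-domain system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amdenm)
```

## The method

aMDeNM (adaptive molecular dynamics with excited normal modes) biases a
thermostatted simulation along collective coordinates without adding a
biasing potential. One campaign consists of many *replicas*; one replica
consists of many *excitation–relaxation cycles*:

1. **Directions.** Low-frequency normal modes are computed once for the
   starting structure. Each replica gets a random unit combination of a
   small selected set of them (here: the 4 modes with the largest RMSF
   contribution over the mobile tail). A direction is kept only if the
   structure displaced 1.0 Å (RMSD) along it differs by more than
   1.15 Å RMSD from the structure displaced along every previously
   accepted direction — a greedy sphere-packing that guarantees replica
   diversity.
2. **Injection.** At the start of each 0.2 ps Langevin segment the
   velocities receive an additive increment along the direction whose
   magnitude is the positive root of
   ½δ² + (p·q)δ = ΔE (mass-weighted momenta p, unit direction q), so the
   kinetic-energy gain is exactly ΔE = 1.25 kcal/mol, independent of the
   current velocities.
3. **Adaptation.** After every segment the net displacement from the
   segment *anchor* (the replica start, or the point of the last update)
   is split into the component along the direction ("theoretical") and
   the rest. If the projected distance is ≥ 0.5 Å and the angle between
   effective and theoretical displacement exceeds 60°, the direction is
   replaced by the normalized difference between the last segment's
   average position and the anchor, and the anchor resets. The original
   mode combination only ever changes through this rule.

Each cycle stores its end conformation; 200 cycles per replica is the
production default.

## The synthetic world

All tests run against a generated two-domain bead system
(`synthetic_spec()` / `make_two_domain_system()`) rather than a protein:

- **Core** (default 40 beads): a Fibonacci lattice on an ellipsoidal
  shell with semi-axis ratios 1.25 : 1.00 : 0.80 about `core_radius`
  (8 Å), plus a seeded 0.3 Å Gaussian jitter. The ratios guarantee three
  distinct principal moments of inertia (relative gaps ≳ 5 %, asserted in
  tests), so the analysis frame's z-axis is well defined. A harmonic
  contact network (all core pairs under 9 Å, `bond_k` =
  100 kcal/mol/Å²) makes the core quasi-rigid.
- **Tail** (default 12 beads, `tail_bond_k` = 20): a wide spiral stalk —
  deliberately non-collinear, since straight chains give an anisotropic
  network spurious soft modes — ending in an ideal helix (radius 2.3 Å,
  100°/bead twist, rise `tail_rise` = 1.5 Å/bead, i→i+3 support bonds).
- **Charges**: the last two tail beads carry −1 (an acidic tip), the two
  core beads nearest the tail anchor +1 (a basic patch). With vacuum
  Coulomb (ε = 1) these form very strong salt-bridge-like traps — which
  is the point: a closed conformation produces residue-pair interaction
  energies below −1 kcal/mol, an open ensemble does not.
- Bead mass 110 amu, one bead per residue, LJ ε = 0.05 kcal/mol,
  r_min/2 = 2.25 Å. All bonded equilibrium values are taken from the
  built geometry, so the structure is a minimum of its bonded terms
  (nonbonded strain of a few kcal/mol remains).

A second generator, `make_ou_trajectory()`, produces frames that are the
reference plus i.i.d. Gaussian noise of known σ. It emulates nothing
dynamical; it exists because RMSF-type estimators have closed forms
against it.

**What a green test does not establish.** The synthetic system has no
sequence, no secondary-structure energetics, no solvent, and its normal
modes come from an elastic network, not the simulation force field. Tests
establish that the *algorithms* are implemented correctly and that the
method's qualitative sampling advantage appears in this stated world —
not that production-scale protein results are reproduced.

## Numerical conventions and parameters

- Units: Å, ps, amu, kcal/mol. 1 kcal/mol = 418.4 amu Å²/ps²;
  k_B = 0.0019872041 kcal/mol/K; Coulomb constant 332.0636 kcal Å/(mol e²).
- Harmonic terms follow CHARMM: bond `k(b−b0)²`, angle `kθ(θ−θ0)²`,
  restraint `k|x−x0|²` (the restraint ladder 10, 1, 0.1 kcal/mol/Å² is
  quoted in this convention). The curvature of a bond at equilibrium is
  therefore 2k, and a diatomic's nonzero mode is 2·(2k)/m.
- Nonbonded truncation: the CHARMM switching polynomial
  S(r) = (r_off²−r²)²(r_off²+2r²−3r_on²)/(r_off²−r_on²)³ between 10 and
  12 Å, applied to **both** LJ and Coulomb. (Production protocols switch
  only vdW and treat electrostatics with PME; PME is out of scope here
  and consistency was preferred.) Forces include the dS/dr term exactly;
  1-2 and 1-3 pairs are excluded.
- Integrator: BAOAB splitting of Langevin dynamics, dt = 2 fs default,
  friction 1 ps⁻¹; friction 0 reduces it to velocity Verlet (energy-drift
  tested). Thermostat noise is seeded; every stochastic entry point takes
  an explicit seed and restores the caller's RNG state.
- Minimization: staged steepest descent with backtracking (monotone
  within a stage) plus conjugate gradient via `stats::optim`.
- ENM defaults: cutoff 12 Å, γ = 1 kcal/mol/Å²; zero-mode tolerance
  `1e-7 · max|λ|`; "low-frequency pool" for mode selection = 20 lowest
  nonzero modes (configurable; the production criterion is stated only as
  "RMSF contribution", so pool + region-summed RMSF is this package's
  documented interpretation).
- Direction metric: modes are orthonormal in mass-weighted coordinates,
  so directions live there; conversion to Cartesian displacement or
  velocity space divides by √m per atom. Displacements are scaled so the
  *unfitted* coordinate RMSD equals the requested amplitude; filter RMSDs
  are likewise unfitted (mode displacements are orthogonal to rigid
  motions to first order, so a fit would be a no-op).
- Projection/angle bookkeeping for adaptation is done on the Cartesian
  displacement field normalized to unit RMSD, so both thresholds are in
  Å on the same scale as the displacement amplitude (with equal bead
  masses this coincides with the mass-weighted metric).

## Design choices on genuinely open points

- **Filter scope**: candidates are compared against *all* previously
  accepted directions (plural reading), greedily in draw order — not a
  global max-diversity optimization.
- **Injection**: additive along the direction with the positive root,
  never a rescaling of the existing component.
- **Adaptation frequency**: checked after every segment.
- **Segment average**: unweighted mean over every integration step of the
  segment (stride configurable).
- **Candidate cap**: 100 × n_replicas draws, then a saturation error that
  reports the acceptance rate. In a 4-mode subspace the 1.15 Å bound
  admits only ~8 mutually diverse directions, so large filtered campaigns
  are impossible here by geometry; the production-scale conformation
  count (183 × 200 = 36,600) is exercised by a bookkeeping-only dry-run
  driver with no forces and frozen coordinates.
- **Analysis frame**: rebuilt from scratch every frame (a pure function
  of the frame); x̂ is the middle principal axis with an intrinsic sign
  (first domain atom on the +x side), ŷ = ẑ × x̂. Any fixed convention
  preserves the track's topology; z-axis sign flips between consecutive
  frames are counted and reported.
- **Graft junction**: no post-graft minimization by default; the junction
  distance is reported instead so the caller can decide.
- **RMSF oracle correction**: per-frame superposition absorbs 6 rigid-body
  degrees of freedom, so the Gaussian fixture's expected RMSF is
  σ√3·√(1−6/3N), about 2 % below the naive σ√3 at N = 52; tests use the
  corrected form.

## Degenerate inputs and tie-breaks

Structures with two equal largest inertia moments are rejected with an
explicit error (the z-axis would be arbitrary). Mode-selection ties break
toward the lower mode index. Kabsch reflections are resolved by flipping
the smallest singular vector. Angle forces clamp cos θ to ±(1−10⁻¹²);
nonbonded pairs under 10⁻⁶ Å raise a singularity error; integration
blow-ups name the offending step.

## Known limitations

Vacuum dielectric 1 with ±1 bead charges makes salt bridges far stronger
than in solvated all-atom systems — trapping is exaggerated, which the
sampling comparison exploits but quantitative energies do not transfer.
The elastic-network modes are not the toy force field's modes (a
numerical-Hessian route is provided and cross-checked on spring-network
fixtures where the two coincide). No solvent, constraints, barostat, PME,
mmCIF, insertion codes, or sidechain chemistry. Campaign-scale runtimes
in tests are scaled down (e.g. 4 replicas × 12 excitations at matched
integration time for the sampling-breadth comparison); nothing about the
algorithm changes with scale, only the statistics get tighter.
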