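---
title: "Structure-based Go-MARTINI topologies and their validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based Go-MARTINI topologies and their validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomartini)
```

## The model

Coarse-grained MARTINI simulations of proteins conventionally keep the fold
together with an elastic network (EN): stiff harmonic springs between all
backbone-bead pairs inside a distance window. The EN is unbreakable, so it
systematically under-estimates the structural fluctuations of flexible,
non-globular proteins — the elongated F-BAR domain of Pacsin1 being the
motivating case. The structure-based (Go-type) alternative replaces the
springs with Lennard-Jones potentials between *native contacts*: attractive
wells that reproduce the native geometry at equilibrium but can break, so
large-amplitude motions such as tip-loop flexing remain accessible.

`gomartini` implements this parameterization as a toolkit with four layers:

1. **Structures** (`read_pdb()`, `write_pdb()`): tidy per-atom tables in nm,
   with hydrogen flagging, altloc resolution and author residue numbering.
2. **Contact maps** (`build_chain_contacts()`, `build_interface_contacts()`,
   `compare_maps()`): the simple cutoff scheme described below.
3. **Topologies** (`make_go_pairs()`, `make_angles()`,
   `make_elastic_bonds()`, `write_itp()`): GROMACS-dialect term lists.
4. **Trajectory statistics** (`rmsf()`, `pca_ensemble()`, `rmsip()`,
   `qab()`, `min_distance_series()`): the quantities used to judge whether a
   coarse-grained model reproduces reference dynamics.

## The cutoff native-contact scheme

For one chain, with residues indexed along the resolved sequence:

* every `(i, i+3)` pair on a continuous stretch of the backbone is a native
  contact unconditionally (`kind = "sequence"`). These short-range contacts
  play the role of the dihedral term in classic Go models; they are only
  meaningful along an unbroken backbone, so a pair spanning a numbering gap
  (unresolved residues) is skipped.
* every pair with `j > i + 3` whose **minimum heavy-atom distance** is
  strictly below the cutoff (default 0.5 nm; 0.45 and 0.55 nm are the other
  values worth scanning) is a spatial contact. Hydrogens never participate.
  Strict inequality makes boundary behaviour deterministic; ties are
  measure-zero.
* `(i, i+1)` and `(i, i+2)` are never contacts — bonds and angles cover them.
* a pair that qualifies both ways (`j = i + 3` and spatially close) is stored
  once, as `kind = "sequence"`; no distance test is applied at `j = i + 3`.

The stored reference distance `r0` is always the C-alpha–C-alpha distance,
because the backbone beads that interact in the coarse-grained model sit at
the C-alpha positions.

Between the two chains of a dimer **no model potential is generated at
all**. Interface pairs found by the same distance rule are recorded as
*virtual* contacts (`kind = "interface"`) and used only for the Q_AB
statistic, which asks whether the force field's own nonbonded interactions
maintain the interface.

Internally the spatial search prunes residue pairs with a centroid +
bounding-radius test before computing exact minimum distances; the test
suite defines correctness by an exhaustive `O(n^2 m^2)` reference
implementation on randomized fixtures, so the pruning is an optimization
only.

## From contacts to topology terms

Each contact becomes a 12-6 Lennard-Jones pair term between backbone beads:

* `sigma_ij = r0 / 2^(1/6)`, which places the potential minimum exactly at
  the native distance;
* `epsilon_ij = lambda * epsilon0` with `epsilon0 = 6.276` kJ/mol, the
  typical hydrogen-bond energy in proteins, and `lambda` a dimensionless
  tuning knob (1.0 is the optimized value for the F-BAR dimer; 1.5 the
  stiffer alternative);
* GROMACS pair coefficients `c6 = 4 eps sigma^6`, `c12 = 4 eps sigma^12`.

Every pair term is emitted together with a matching `[ exclusions ]` entry.
This is essential: the exclusion removes the force field's own nonbonded
interaction between the two beads, so `epsilon_ij` is the *true* well depth
rather than an increment on top of it. The unit tests assert the resulting
identities `U(r0) = -epsilon_ij` and `U(sigma) = 0` to 1e-10 relative for
every emitted term.

Backbone angles get their equilibrium values from the native structure (the
model biases toward the native geometry, so using the native angle is the
consistent choice — not the force field's secondary-structure defaults). The
force constant is secondary-structure dependent: 700 kJ/mol where the
central residue is helical (DSSP classes H, G and I all count as helix, as
`martinize` treats them), 20 kJ/mol otherwise. Prolines at helix kinks
(author residues 145 and 221 in Pacsin1; `kink_residues` is user-settable)
are forced to the soft constant because a stiff angle at a kink would fight
the native geometry. The override keys on the *central* residue of the
triple, since the named constant is a per-angle quantity and the kink
proline sits at the angle's apex.

Backbone connectivity uses harmonic bonds between consecutive beads at the
native C-alpha spacing with the conventional MARTINI constant
1250 kJ/mol/nm^2 (the reference parameterization is silent on bonds, which
it delegates to `martinize`). No dihedral terms are emitted: the
unconditional `(i, i+3)` contacts provide that bias.

The conventional elastic network is available for comparison:
springs of 500 kJ/mol/nm^2 between intra-chain bead pairs with sequence
separation >= 3 and native distance in the closed window [0.5, 1.2] nm.
Inclusive bounds read the window limits as part of the set; with the
separation rule mirroring `martinize` behaviour. The published per-chain
bond counts for the Pacsin1 dimer (2688/2646) serve as the calibration
oracle for this rule; the exact neighbor-exclusion convention of a given
`martinize` version is the first knob to revisit if a discrepancy appears.

## Trajectory statistics

All statistics operate on a `cg_ensemble`: frames over a fixed atom set, in
nm. The default analysis window is the **last half** of the trajectory
(0-based frame index >= ceiling(n/2)), the standard equilibrated window for
fluctuation statistics; PCA defaults to all frames since it describes the
sampled conformational space rather than an equilibrium average.

* **Superposition** is a two-pass Kabsch fit: fit all frames to the first,
  compute the mean structure, refit to the mean. The rotation is always
  proper (no reflections); rank-deficient selections are flagged rather than
  rejected. The test suite cross-checks the RMSD against an independent
  quaternion-method implementation and against `bio3d`.
* **RMSF** is the per-atom root-mean-square deviation from the window-mean
  position. For isotropic Gaussian displacements of per-axis standard
  deviation *s* it converges to *s* sqrt(3), which the tests verify by
  simulation.
* **PCA** diagonalizes the covariance of the flattened selected coordinates
  (mass-unweighted: backbone beads have near-uniform mass). Eigenvalues are
  variances in nm^2; the eigenvalue sum equals the covariance trace, and
  projections reconstruct the centered frames exactly when all modes are
  kept — both asserted as invariants.
* **RMSIP** over the first 10 eigenvectors quantifies the overlap of two
  essential subspaces: 1 for identical subspaces, 0 for orthogonal ones,
  symmetric, and invariant to rotations within either subspace.
* **Joint PCA** superposes every frame of every trajectory onto one common
  reference (the grand mean of pooled pre-fitted frames) and projects each
  trajectory onto shared components, so different models of the same protein
  can be compared in one essential subspace.
* **Q_AB** counts the fraction of virtual interface contacts present per
  frame; a contact is present when the bead distance is below
  `1.5 sigma_ij = (1.5 / 2^(1/6)) r0`. The code uses the exact factor
  (1.336348...), not the commonly quoted 1.34 approximation, so the
  threshold is consistent with the LJ length parameter to machine precision.
* **Minimum-distance series** between two selections (e.g. a wedge-loop
  lysine versus lipid phosphate beads) is the membrane-binding metric.

## Synthetic fixtures: what they do and do not show

The generators in this package *are* the study conditions of the test suite:

* `make_ideal_helix()` — a regular helix (rise 0.15 nm, twist 100 degrees,
  radius 0.23 nm, hence the canonical 0.38 nm C-alpha spacing) with one
  dummy side-chain heavy atom per residue, offset along the helix axis
  toward the next turn. That offset mimics the backbone carbonyl direction
  that mediates real helical `i, i+4` packing, so the fixture shows the
  helix-characteristic contact pattern (all `i, i+3` plus all `i, i+4` at a
  0.5 nm cutoff) with only two heavy atoms per residue.
* `make_toy_dimer()` — two antiparallel helix copies with `k` designed
  interface pairs at a stated distance (default 0.45 nm) and all other
  inter-chain distances kept above 0.6 nm, so the designed pairs are exactly
  the interface map. Chains are related by a proper rigid transform, making
  the intra-chain maps identical — the homodimer symmetry that
  `compare_maps()` should report as 100% common.
* `make_random_coil()` — a compact self-avoiding C-alpha walk; the fixture
  for brute-force oracle equivalence, cutoff monotonicity and elastic-bond
  window tests.
* `make_gaussian_ensemble()` — frames drawn from a known low-rank Gaussian:
  reference + sum of `sqrt(variance_k) z_k e_k` over orthonormal planted
  modes. Because the planted spectrum is ground truth, PCA eigenvalue
  recovery (5% at 5000 frames for variances 1.0/0.5/0.1 nm^2), PC1 mode
  overlap (> 0.99 at 1000 frames) and RMSF limits are exact, falsifiable
  claims.

What passing these tests does **not** show: agreement with microsecond-scale
membrane simulations. The published validation numbers for the F-BAR system
(RMSIP of 0.691 between the optimized coarse-grained model and the all-atom
reference, interface Q_AB averages of 0.83–0.94, per-residue RMSF profiles,
membrane binding and dimer-dimer assembly) require production molecular
dynamics on cluster hardware with a full membrane, which is out of scope
here. The synthetic ensembles validate that the *statistics* are computed
correctly, not that any particular force field reproduces any particular
protein's dynamics. Likewise the Gaussian ensembles are harmonic by
construction: they exercise none of the anharmonic, multi-basin behaviour
that makes the breakable Go contacts interesting in production use.

Two published calibration counts do depend on a real structure: the 793
common contacts (93%/94% of per-chain totals) and the 2688/2646 per-chain
elastic bonds of the Pacsin1 F-BAR dimer (PDB 3HAH). The structure is not
bundled with the package (it is several hundred kilobytes); the calibration
tests locate a local copy or download it, and report a clear failure when
neither is possible. Those counts were obtained on a loop-completed model of
the dimer, so a raw crystal structure can legitimately differ by a few
contacts; the tests flag deviations beyond 2%.

## Numerical and interface choices

* All coordinates are nm internally; PDB I/O converts from/to angstrom, and
  the command-line front end accepts cutoffs in angstrom behind an explicit
  `--angstrom` flag.
* Altloc resolution keeps the highest-occupancy conformer (ties: first
  seen); HETATM records are excluded; modified residues deposited as ATOM
  records are kept. Element symbols come from the PDB element column with
  name-based fallback for minimal writers.
* Residues are ordered by author number with insertion codes alphabetical;
  internal indexing is contiguous per chain, but every user-facing table
  reports author numbering, which is how residues are cited (K123, Pro145,
  Pro221).
* Multi-model files default to the first model (`model_index = 0`).
* Degenerate cases are explicit: empty heavy-atom residues error in distance
  computations; chains shorter than three beads yield empty angle lists;
  ensembles with inconsistent atom counts are rejected, not repaired.
* Test problem sizes are chosen for exactness at small scale: oracle
  equivalence on 12–30-residue fixtures, parameter recovery on 30-atom
  ensembles of 1000–5000 frames, a 10 000-frame ensemble for the RMSF limit.
  The whole suite runs in a few seconds.

## Known limitations

* Only backbone (C-alpha) beads are parameterized: no MARTINI side-chain
  beads, bead typing, or lipid/solvent topologies. The `.itp` output is a
  backbone include file, not a complete simulation system.
* The atomic-overlap (OV) and chemistry-based (rCSU) contact definitions
  used by the original Go-MARTINI tooling are not implemented; the cutoff
  scheme replaces them by design.
* Contact maps are defined from one static structure; symmetrizing over
  homodimer chains or filtering by contact persistence in reference
  trajectories are natural refinements left to the user.
* DSSP output parsing covers the classic fixed-column format; the package
  does not run DSSP itself, and a plain per-residue code string is accepted
  everywhere a DSSP file is.
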