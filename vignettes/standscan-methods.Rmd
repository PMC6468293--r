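---
title: "Methods: structural analysis of resting-form STAND ATPases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of resting-form STAND ATPases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standscan)
```

## Scope and scientific background

STAND ATPases (signal transduction ATPases with numerous domains) rest as
autoinhibited monomers in which a conserved NOD module — nucleotide-binding
domain (NBD), helical domain (HD) and winged-helix domain (WHD) — clamps an
ADP molecule, and multimerize into signalling hubs once inducer binding
opens the NOD. In resting forms the NBD is held closed by interfaces with
the arm domain and, as crystal structures of TPR-sensor STANDs show, with
the sensor domain as well. `standscan` packages the geometric measurements
that characterize such resting forms:

* rigid-body (Kabsch) superposition of the copies in an asymmetric unit;
* Shrake–Rupley solvent-accessible surface areas (SASA) and domain-pair
  buried-interface areas;
* ligand-pocket and interdomain residue-contact mapping;
* the ABA/BAB turn-packing-angle statistic that classifies the curvature of
  TPR-like α-solenoids (arm and sensor domains);
* residue-pair distances for engineered-cysteine disulfide feasibility and
  surface-patch spans (the register logic of inhibitor binding).

A synthetic-structure generator makes each stage testable against known
ground truth without downloading any structure.

## Structure model and input conventions

A structure is a tibble with one row per atom (`chain`, `resno`, `ins`,
`resid`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`, `is_hetero`, `vdw`),
so every analysis composes with ordinary data-frame tooling. Conventions,
chosen once:

* **Author residue numbering** everywhere, 1-based inclusive ranges,
  because domain boundaries and mutation sites in the literature are cited
  in author numbering.
* **Altloc resolution**: keep the highest-occupancy conformer; ties break
  alphabetically by altloc id. Deterministic and standard practice.
* **Van der Waals radii** (Bondi-style): C 1.70, N 1.55, O 1.52, S 1.80,
  P 1.80, H 1.20 Å; unknown elements get 1.70 Å with a warning. A fixed
  table keeps SASA reproducible.
* **Hydrogens** are dropped on load (low-resolution crystal structures
  deposit none; all geometry here is heavy-atom based), **waters** too
  unless retained explicitly.
* A residue counts as modeled when it has at least one deposited atom.

## Superposition

`kabsch_superpose()` is the SVD solution of the orthogonal Procrustes
problem with the usual determinant correction, so the returned rotation is
always proper. Pairing between chains (`map_common_atoms()`) is by author
residue number, insertion code and atom name; unmatched residues are
dropped. Degenerate inputs (fewer than 3 pairs, collinear point sets) are
errors rather than silently unstable fits. The test suite checks the exact
identities (zero RMSD on self, recovery of a known rotation), equality with
a brute-force minimization over rotations on small point sets, and
agreement with the independent `bio3d` implementation.

## Solvent-accessible surface and buried interfaces

`shrake_rupley()` samples each atom's expanded sphere (radius `vdw + probe`)
at `n_points` directions from a Fibonacci lattice with the standard
half-step offset — deterministic, so areas are bit-reproducible — and scores
a point buried when it falls inside any neighbour's expanded sphere.
Defaults: probe 1.4 Å (water), 960 points, heavy atoms only. At 960 points
the isolated-sphere area is exact, the two-sphere spherical-cap closed form
is matched to well under 1%, and refining to 4000 points moves 50-atom
cluster totals by well under 1%.

The buried interface area between domain selections A and B is

$$\mathrm{buried}(A,B) = \tfrac12\,(\mathrm{SASA}_A + \mathrm{SASA}_B -
\mathrm{SASA}_{AB}),$$

the per-side average loss of accessible area, clamped at zero. Two
accounting contexts exist because per-domain-pair numbers imply pairwise
accounting: the default **isolated pair** extracts the two selections from
the structure; a **full-structure** mode instead measures the loss of
accessible area within the intact molecule when the partner is deleted.
Ligands and waters are excluded from interface calculations. Published
interface areas rarely state probe, radii set or software, so comparisons
against literature values should allow a generous (±20%) method tolerance.

Residue contacts (`find_contacts()`) are residue pairs whose minimum
heavy-atom distance is within the cutoff (default 4.0 Å). A contact is
classed `hbond` when the closest N/O–N/O pair is within 3.5 Å; donor and
acceptor chemistry is deliberately not inferred, which is the
resolution-appropriate reading for structures that deposit no hydrogens.
The spatial grid used for neighbour search is an implementation detail: its
output is identical to the all-pairs computation, which the tests enforce.

## The ABA/BAB packing-angle statistic

A TPR-like solenoid stacks helical hairpins so that the first helices build
one face (A) and the second helices the other (B). For every interior helix
the two bracketing turns are taken as vectors from the Cα of the last
residue of the preceding helix to the Cα of the first residue of the
following helix, projected onto the plane perpendicular to that helix's
axis; the unsigned angle between the projections is a **BAB angle** at an A
helix and an **ABA angle** at a B helix. When BAB angles exceed ABA angles
the slab curves toward the A face — the canonical TPR curvature — and the
reverse ordering curves it toward B.

Design choices where the definition left room:

* **Axis fitting**: the Cα trace is smoothed with sliding 4-residue
  midpoints and the axis is the principal direction of the centered
  midpoints, oriented N→C. Robust for 10–15-residue TPR helices, where a
  fit to raw Cα positions would be dominated by the helical wind.
* **Turn vector**: the Cα-endpoint difference defined above — the simplest
  reading of "the direction of the turn". An alternative (helix-axis
  termini) would differ by a bounded offset; because of this freedom,
  local-anomaly conclusions on real structures are treated as orderings,
  never as magnitudes.
* **Unsigned angles** in [0°, 180°]; no sign convention is imposed.
* **Flat band**: |mean BAB − mean ABA| ≤ 2° is called `flat`. On noisy
  synthetic solenoids (σ = 0.2 Å) the fitting noise of the mean difference
  stays below this band, so calls outside it are meaningful.
* **Undefined projections**: a turn nearly parallel to the helix axis
  (projected length < 10⁻³ of the original) yields an undefined angle,
  which is excluded from the means and reported rather than propagated.
* **Anomalies**: after the global call, each interior helix is compared
  with the mean of its flanking opposite-label angles; helices whose local
  ordering opposes the global call are flagged. This is how a local
  curvature reversal — e.g. a single depressed BAB angle inside an
  otherwise A-curved solenoid, the signature of a curvature change at a
  domain junction — is surfaced.
* **Helix tables** for real structures are configuration data (curated
  boundaries), not code; the geometric fallback detector exists for
  synthetic traces. The bundled PH0952 configuration marks its helix
  endpoints as approximate annotation to be replaced by curated values.

## The synthetic-structure generator

The generator is first-class, tested code; it defines the conditions under
which the method is validated.

* `make_ideal_helix()` builds Cα traces with canonical parameters (rise
  1.5 Å/residue, twist 100°/residue, radius 2.3 Å); the consecutive-Cα
  distance then has the closed form `sqrt(rise² + (2 r sin(twist/2))²)` ≈
  3.83 Å, which the tests pin.
* `make_solenoid()` stacks antiparallel hairpins (helix length 12, axis
  separation 10 Å, stack spacing 10 Å, 3-residue interpolated turns, four
  to six repeats — dimensions typical of TPR slabs). Successive repeats are
  related by a screw transform: translation along the stacking direction
  plus rotation about an axis parallel to the helix axes on the A side of
  the slab. Zero rotation gives a straight ladder with ABA = BAB exactly;
  in this construction the ground-truth mean difference equals the
  per-repeat rotation angle, and `solenoid_with_curvature()` prescribes the
  difference directly by root finding. Ground truth is computed from the
  construction frame — exact turn endpoints and exact transform-propagated
  axis directions — before any noise, a route independent of the fitted
  pipeline it validates. Transforms that collapse repeats onto each other
  (any cross-repeat Cα–Cα < 1 Å) are rejected.
* `perturb()` adds seeded isotropic Gaussian noise (the displacement RMS
  approaches σ√3, which the tests check at 10⁴ atoms), and
  `make_sphere_cluster()` provides seeded atom clouds for the SASA oracles.
  All generators take explicit seeds and leave the caller's RNG stream
  untouched.

What the generator does **not** emulate: side chains, Ramachandran-valid
backbones, crystal packing, anisotropic coordinate error, or sequence-
dependent helix irregularity. Passing the synthetic recovery tests
therefore demonstrates the correctness of the geometry and the stability of
the statistic under isotropic noise — not that curated helix boundaries on
a real structure are right, which remains the user's responsibility.

## Distance analyses

Engineered-cysteine disulfide feasibility uses Cβ–Cβ distances (Cβ falls
back to Cα for glycine, recorded per pair) against a default threshold of
7.0 Å — deliberately permissive, since catalyzed oxidation of flexible
surface side chains traps transient proximity well beyond ideal S–S
geometry. Feasibility is monotone in the threshold by construction. Patch
spans report the exact minimum and maximum over all inter-patch atom pairs;
patch membership must be listed explicitly because published "patches" are
usually open-ended. Published spans of the form "~45–66 Å (depending on the
atoms considered)" are matched qualitatively, never asserted numerically.

## Pipeline determinism and problem sizes

`analyze()` validates the whole configuration before computing anything,
then runs census → cell → superpositions → interfaces → ligand pocket →
solenoids → distances in fixed order; `write_report()` emits JSON with no
timestamps, so identical inputs give byte-identical reports. The
configuration text is echoed into the report for provenance.

The validation suite runs on generated structures of modest size — 50-atom
clusters for SASA oracles, 4–7-helix solenoids (~100–150 residues), 10⁴
atoms for the noise-calibration check — sizes at which every oracle
(closed forms, brute-force enumeration, Monte-Carlo sampling, independent
reference implementations) is exact or tightly converged. The
`scripts/acceptance.R` report recomputes the same headline quantities from
scratch at those sizes, including an asymmetric-unit emulation: four
independently noise-perturbed copies (σ = 0.15 Å) of one solenoid chain,
whose maximum pairwise Cα RMSD (~σ√6 ≈ 0.37 Å) mirrors the near-identity of
crystallographically independent copies of a resting-form structure.

## Known limitations

* mmCIF parsing relies on `bio3d`'s reader (flagged beta upstream);
  exotic mmCIF files (multi-model, multi-datablock) are out of scope.
* The SASA implementation is pure R; structures of ~20k atoms take seconds,
  not milliseconds. Interface calculations on extracted domain pairs are
  fast regardless.
* Curvature calls depend on the helix table; mis-assigned helix boundaries
  shift individual angles by several degrees. The statistic is designed
  for comparisons of means, and single-helix anomalies should be read as
  orderings.
* No symmetry expansion: analyses see exactly the deposited asymmetric
  unit.
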