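# standscan

Structural analysis of resting-form STAND ATPases and other α-solenoid
proteins, in R.

STAND ATPases (APAF1, NOD-like receptors, the bacterial transcription
activator MalT, archaeal regulators such as PH0952) rest as autoinhibited
monomers: a conserved NOD module (NBD–HD–WHD) clamps an ADP molecule, and
the arm and sensor domains pin the NBD closed until inducer binding opens
the switch. Characterizing a resting-form crystal structure means asking a
recurring set of geometric questions, and `standscan` answers them from one
atom-table data model:

* **Superposition** — Kabsch (SVD) rigid-body fits with proper-rotation
  enforcement; all pairwise Cα RMSDs between the copies of an asymmetric
  unit (`kabsch_superpose()`, `superpose_all_chains()`).
* **Surfaces** — deterministic Shrake–Rupley SASA on a Fibonacci lattice
  and domain-pair buried-interface areas,
  `buried = (SASA_A + SASA_B − SASA_AB)/2`
  (`shrake_rupley()`, `buried_interface_area()`).
* **Contacts** — residue-level ligand-pocket and interdomain contact maps
  with a resolution-appropriate H-bond class (`find_contacts()`).
* **Solenoid curvature** — the ABA/BAB turn-packing-angle statistic for
  TPR-like slabs: at each interior helix, the two bracketing turn vectors
  are projected onto the plane perpendicular to the fitted helix axis;
  mean BAB > mean ABA curves the slab toward the A face, the reverse
  toward B, and local reversals are flagged as anomalies
  (`packing_angles()`, `classify_curvature()`).
* **Cross-link geometry** — Cβ–Cβ disulfide feasibility for engineered
  cysteine pairs and exact min/max spans between surface patches
  (`pair_distances()`, `disulfide_feasibility()`, `patch_span()`).
* **Synthetic structures** — ideal helices, hairpin solenoids with exact
  ground-truth packing angles, seeded noise and sphere clusters, so every
  stage is testable without downloads (`make_ideal_helix()`,
  `make_solenoid()`, `perturb()`, `make_sphere_cluster()`).
* **Pipeline** — `analyze()` runs census → cell → superpositions →
  interfaces → ligand pocket → solenoids → distances from one YAML
  configuration and writes deterministic JSON/TSV reports. A bundled
  configuration (`inst/extdata/ph0952.yaml`) encodes the PH0952 domain
  architecture (NBD 102–262, HD 263–316, WHD 317–393, arm 394–496, sensor
  497–748, interfaces NBD:WHD / NBD:arm / NBD:sensor, ADP pocket, arm and
  sensor helix tables).

Structures are tibbles (one row per atom), every analysis takes the data
frame first and returns a tibble or a tidy-able object (`tidy()`,
`glance()`, `autoplot()`), so everything chains with the pipe. PDB and
mmCIF are read and written via `bio3d` plus a cell-record parser.

## Worked example

```r
library(standscan)

# a 5-repeat TPR-like solenoid built with a prescribed curvature of 8 deg
sol <- solenoid_with_curvature(8, n_repeats = 5)
report <- packing_angles(sol$annotation, sol$structure)
report
#> <angle_report: 8 interior helices, mean ABA 146.00 deg, mean BAB 154.00 deg, curvature toward-A>
glance(report)
#> # A tibble: 1 × 5
#>   mean_ABA mean_BAB delta curvature n_anomalies
#>      <dbl>    <dbl> <dbl> <chr>           <int>
#> 1     146.     154.  8.00 toward-A            0
```

The BAB angles (at A helices) exceed the ABA angles by the prescribed 8°,
so the slab is called curved toward its A face — the canonical TPR
curvature. A noisy copy of the same chain superposes back onto it at the
RMSD expected for σ = 0.15 Å coordinate noise (σ√6 ≈ 0.37 Å between two
noisy copies, ~σ√3 against the clean chain):

```r
fit <- kabsch_superpose(
  coords_matrix(perturb(sol$structure, 0.15, seed = 1)),
  coords_matrix(sol$structure)
)
fit
#> <superposition: rmsd 0.2506 A over 147 atoms>
```

Surface areas come with closed-form anchors — an isolated carbon atom with
a 1.4 Å probe is exactly `4π(1.70+1.4)² ≈ 120.76 Å²`:

```r
one <- as_structure(data.frame(chain = "A", resno = 1, resid = "SPH",
                               atom = "X", element = "C", x = 0, y = 0, z = 0))
glance(shrake_rupley(one))
#> # A tibble: 1 × 4
#>   total n_atoms probe n_points
#>   <dbl>   <int> <dbl>    <int>
#> 1  121.       1   1.4      960
```

To analyse a real structure end to end:

```r
report <- analyze("6MFV.cif",
                  system.file("extdata", "ph0952.yaml", package = "standscan"))
write_report(report, "report.json", tsv_dir = "report_tsv")
```

A thin command-line wrapper lives at `inst/scripts/standscan.R`
(`Rscript standscan.R analyze --config ph0952.yaml --structure 6MFV.cif
--out report.json`).

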