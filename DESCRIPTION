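Package: standscan
Title: Structural Analysis of STAND Protein Resting Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural dissection of autoinhibited (resting-form)
    STAND ATPases and other alpha-solenoid proteins: rigid-body (Kabsch)
    superposition of asymmetric-unit copies, Shrake-Rupley solvent-accessible
    surface areas and domain-pair buried-interface areas, ligand-pocket and
    interdomain residue-contact mapping, the ABA/BAB turn-packing-angle
    statistic that classifies tetratricopeptide-repeat solenoid curvature,
    and residue-pair distance analyses for engineered-cysteine cross-link
    feasibility and surface-patch spans. A synthetic-structure generator
    (ideal helices, helical-hairpin solenoids with known ground-truth packing
    angles, random atom clouds) makes every stage testable without structure
    downloads. Structures are held as one-row-per-atom tibbles so analyses
    compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
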