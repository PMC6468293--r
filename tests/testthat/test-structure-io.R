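test_that("structures round-trip through PDB and mmCIF at serialization precision", {
  sol <- make_solenoid(3, rotation_deg = 5)$structure
  for (fmt in c("pdb", "cif")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(sol, f)
    back <- read_structure(f)
    expect_equal(nrow(back), nrow(sol))
    expect_equal(coords_matrix(back), coords_matrix(sol),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(back$resno, sol$resno)
    # write-read-write is byte-stable
    f2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties alphabetical", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      10.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA AALA A   2       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BALA A   2       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      4  CA AALA A   3       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      5  CA BALA A   3       4.000   0.000   0.000  0.50 10.00           C",
    "END"
  ), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$x[s$resno == 2], 2.0) # occupancy 0.60 wins
  expect_equal(s$x[s$resno == 3], 3.0) # tie -> altloc A
})

test_that("waters and hydrogens are dropped by default but retainable", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00 10.00           H",
    "HETATM    3  O   HOH A 101       5.000   0.000   0.000  1.00 10.00           O",
    "HETATM    4  PB  ADP A 201       8.000   0.000   0.000  1.00 10.00           P",
    "END"
  ), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 2)
  expect_equal(ligand_residues(s)$resid, "ADP")
  full <- read_structure(f, keep_waters = TRUE, keep_hydrogens = TRUE)
  expect_equal(nrow(full), 4)
})

test_that("unknown elements get the default radius with a warning", {
  expect_warning(r <- vdw_radius("ZN"), "default")
  expect_equal(r, 1.70)
  expect_silent(vdw_radius("ZN", quiet = TRUE))
  expect_equal(vdw_radius(c("C", "N", "O", "S", "P", "H"), quiet = TRUE),
               c(1.70, 1.55, 1.52, 1.80, 1.80, 1.20))
})

test_that("cell parameters are captured from both formats and absence is a value", {
  sol <- make_solenoid(2)$structure
  attr(sol, "cell") <- list(a = 96.13, b = 96.13, c = 584.3,
                            alpha = 90, beta = 90, gamma = 120,
                            space_group = "P 65")
  for (fmt in c("pdb", "cif")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(sol, f)
    cell <- get_cell(read_structure(f))
    expect_equal(cell$c, 584.3, tolerance = 1e-6)
    expect_equal(cell$gamma, 120)
    expect_equal(cell$space_group, "P 65")
  }
  bare <- make_solenoid(2)$structure
  expect_equal(nrow(get_cell(bare)), 0)
})

test_that("write_structure refuses degenerate and oversized-for-PDB input", {
  empty <- as_structure(data.frame(
    chain = character(), resno = integer(), resid = character(),
    atom = character(), element = character(),
    x = double(), y = double(), z = double()
  ))
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_structure(empty, f), "empty")
  big_resno <- as_structure(data.frame(
    chain = "A", resno = 123456, resid = "ALA", atom = "CA",
    element = "C", x = 0, y = 0, z = 0
  ))
  expect_error(write_structure(big_resno, f), "mmCIF")
  fc <- withr::local_tempfile(fileext = ".cif")
  expect_silent(write_structure(big_resno, fc))
  expect_equal(read_structure(fc)$resno, 123456L)
})

test_that("atom selection is deterministic, conservative, and validates input", {
  h <- make_ideal_helix(20)
  expect_error(atom_selection(range = c(500, 400)), "start > end")
  expect_error(select_atoms(h, atom_selection(chain = "Z")), "No such chain")
  # empty range on an existing chain is empty, not an error
  expect_equal(nrow(select_atoms(h, atom_selection(chain = "A", range = c(500, 600)))), 0)
  # conservation: full-range selection returns every atom exactly once
  all_sel <- select_atoms(h, atom_selection(chain = "A"))
  expect_equal(nrow(all_sel), nrow(h))
  expect_false(any(duplicated(paste(all_sel$resno, all_sel$atom))))
  # selection algebra: disjoint ranges union
  s1 <- select_atoms(h, atom_selection(range = c(1, 10)))
  s2 <- select_atoms(h, atom_selection(range = c(11, 20)))
  expect_equal(nrow(s1) + nrow(s2), nrow(all_sel))
  expect_length(intersect(s1$resno, s2$resno), 0)
})

test_that("chain census counts residues with at least one deposited atom", {
  sol <- make_solenoid(3)$structure
  cen <- chain_census(sol)
  expect_equal(cen$n_residues, length(unique(sol$resno)))
  expect_equal(cen$n_atoms, nrow(sol))
})

test_that("domain maps read from YAML with overlap flagging and name checks", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "domains:",
    "  - {name: NBD, chain: A, start: 102, end: 262}",
    "  - {name: HD,  chain: A, start: 263, end: 316}"
  ), f)
  m <- read_domain_map(f)
  expect_equal(m$name, c("NBD", "HD"))
  writeLines(c(
    "domains:",
    "  - {name: X, chain: A, start: 1, end: 50}",
    "  - {name: Y, chain: A, start: 40, end: 80}"
  ), f)
  expect_warning(read_domain_map(f), "overlap")
  writeLines(c(
    "domains:",
    "  - {name: X, chain: A, start: 1, end: 50}",
    "  - {name: X, chain: A, start: 60, end: 80}"
  ), f)
  expect_error(read_domain_map(f), "unique")
})
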