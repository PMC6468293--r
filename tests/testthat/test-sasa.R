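single_atom <- function(x = 0, y = 0, z = 0, vdw = 1.70, resno = 1) {
  data.frame(chain = "A", resno = resno, resid = "SPH", atom = "X",
             element = "C", x = x, y = y, z = z, vdw = vdw)
}

test_that("an isolated sphere matches the closed form exactly", {
  s <- as_structure(single_atom())
  for (np in c(96, 960)) {
    r <- shrake_rupley(s, probe = 1.4, n_points = np)
    expect_equal(r$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
  }
  # probe 0 reduces to the bare vdW sphere
  expect_equal(shrake_rupley(s, probe = 0)$total, 4 * pi * 1.70^2, tolerance = 1e-9)
})

test_that("two overlapping spheres match the spherical-cap closed form within 1%", {
  cases <- list(
    list(r = c(1.70, 1.70), d = 3.0),
    list(r = c(1.70, 1.52), d = 2.5),
    list(r = c(1.80, 1.55), d = 3.2)
  )
  for (cs in cases) {
    s <- as_structure(rbind(
      single_atom(vdw = cs$r[1], resno = 1),
      single_atom(x = cs$d, vdw = cs$r[2], resno = 2)
    ))
    res <- shrake_rupley(s, probe = 1.4, n_points = 960)
    expected <- two_sphere_areas(cs$r[1] + 1.4, cs$r[2] + 1.4, cs$d)
    expect_equal(res$per_atom$area, expected, tolerance = 0.01, ignore_attr = TRUE)
    expect_equal(res$total, sum(expected), tolerance = 0.01)
  }
})

test_that("random clusters agree with an independent Monte-Carlo oracle within 2%", {
  cl <- make_sphere_cluster(50, radii = c(1.52, 1.70, 1.80), box = 14, seed = 31)
  ours <- shrake_rupley(cl, probe = 1.4, n_points = 960)$total
  oracle <- mc_sasa(cl, probe = 1.4, n = 20000, seed = 99)
  expect_lt(abs(ours - oracle) / oracle, 0.02)
})

test_that("sampling density has converged at 960 points", {
  cl <- make_sphere_cluster(50, radii = c(1.52, 1.70, 1.80), box = 14, seed = 8)
  a960 <- shrake_rupley(cl, 1.4, 960)$total
  a4000 <- shrake_rupley(cl, 1.4, 4000)$total
  expect_lt(abs(a4000 - a960) / a4000, 0.01)
})

test_that("adding an atom never increases any other atom's accessible area", {
  cl <- make_sphere_cluster(25, box = 9, seed = 4)
  base <- shrake_rupley(cl, 1.4, 960)$per_atom$area
  extra <- rbind(tibble::as_tibble(cl), tibble::as_tibble(as_structure(
    single_atom(x = 4.5, y = 4.5, z = 4.5, resno = 26)
  )))
  grown <- shrake_rupley(as_structure(extra), 1.4, 960)$per_atom$area
  expect_true(all(grown[1:25] <= base + 1e-9))
  expect_equal(sum(shrake_rupley(cl, 1.4, 960)$per_atom$area),
               shrake_rupley(cl, 1.4, 960)$total, tolerance = 1e-6)
})

test_that("buried interface area is symmetric, clamped, and probe-monotone", {
  sol <- make_solenoid(2, rotation_deg = 0)$structure
  ann <- make_solenoid(2, rotation_deg = 0)$annotation
  sel_a <- atom_selection(range = c(ann$start[1], ann$end[1]))
  sel_b <- atom_selection(range = c(ann$start[2], ann$end[2]))
  ab <- buried_interface_area(sol, sel_a, sel_b)
  ba <- buried_interface_area(sol, sel_b, sel_a)
  expect_gt(ab, 0) # packed hairpin helices do touch
  expect_identical(ab, ba)
  # larger probe occludes more
  expect_lte(buried_interface_area(sol, sel_a, sel_b, probe = 0), ab)
  # distant partners bury nothing
  far <- as_structure(rbind(single_atom(resno = 1), single_atom(x = 50, resno = 2)))
  expect_equal(buried_interface_area(far, atom_selection(residues = 1),
                                     atom_selection(residues = 2)), 0)
  # overlapping or empty selections are refused
  expect_error(buried_interface_area(sol, sel_a, sel_a), "overlap")
  expect_error(buried_interface_area(sol, sel_a, atom_selection(range = c(5000, 5001))),
               "no atoms")
})

test_that("full-structure interface context reports less or equal burial than isolation", {
  sol <- make_solenoid(3, rotation_deg = 5)
  ann <- sol$annotation
  sel_a <- atom_selection(range = c(ann$start[2], ann$end[2]))
  sel_b <- atom_selection(range = c(ann$start[3], ann$end[3]))
  iso <- buried_interface_area(sol$structure, sel_a, sel_b)
  ctx <- buried_interface_area(sol$structure, sel_a, sel_b, context = "full-structure")
  expect_gte(iso, 0)
  expect_gte(ctx, 0)
})

test_that("contact lists equal the naive all-pairs computation", {
  set.seed(12)
  n <- 200
  s <- as_structure(data.frame(
    chain = rep(c("A", "B"), each = n / 2), resno = rep(seq_len(n / 2), 2),
    resid = "ALA", atom = "CA",
    element = sample(c("C", "N", "O", "S"), n, TRUE),
    x = runif(n, 0, 25), y = runif(n, 0, 25), z = runif(n, 0, 25)
  ))
  got <- find_contacts(s, atom_selection(chain = "A"), atom_selection(chain = "B"),
                       cutoff = 4.5)
  a <- s[s$chain == "A", ]; b <- s[s$chain == "B", ]
  dm <- sqrt(outer(rowSums(coords_matrix(a)^2), rowSums(coords_matrix(b)^2), "+") -
               2 * tcrossprod(coords_matrix(a), coords_matrix(b)))
  naive <- which(dm <= 4.5, arr.ind = TRUE)
  naive_pairs <- unique(data.frame(ra = a$resno[naive[, 1]], rb = b$resno[naive[, 2]]))
  expect_equal(nrow(got), nrow(naive_pairs))
  # every reported minimum distance is recomputable by direct enumeration
  for (k in seq_len(min(nrow(got), 20))) {
    expect_equal(got$min_dist[k],
                 min(dm[a$resno == got$resno_a[k], b$resno == got$resno_b[k]]),
                 tolerance = 1e-9)
  }
})

test_that("contacts are classed hbond only for close N/O-N/O pairs", {
  s <- as_structure(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1, 1, 1, 2),
    resid = c("SER", "SER", "SER", "ALA"),
    atom = c("OG", "CB", "N", "CB"), element = c("O", "C", "N", "C"),
    x = c(0, 0, 3.2, 0), y = c(0, 1.2, 0, 3.4), z = 0
  ))
  ct <- find_contacts(s, atom_selection(chain = "A"), atom_selection(chain = "B"),
                      cutoff = 4.0)
  expect_equal(ct$class[ct$resno_b == 1], "hbond") # O...N at 3.2 A
  expect_equal(ct$class[ct$resno_b == 2], "vdw")   # only C...C close
  # selections farther apart than cutoff give an empty, well-typed table
  far <- find_contacts(s, atom_selection(chain = "A", residues = 1),
                       atom_selection(chain = "B", residues = 2), cutoff = 1.0)
  expect_equal(nrow(far), 0)
  expect_true(all(c("min_dist", "class") %in% names(far)))
})
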