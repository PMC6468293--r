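test_that("translation-only solenoids are flat: ABA equals BAB", {
  sol <- make_solenoid(5, rotation_deg = 0)
  expect_lt(abs(sol$ground_truth$delta), 1e-9)
  rep <- packing_angles(sol$annotation, sol$structure)
  expect_lt(abs(rep$mean_BAB - rep$mean_ABA), 1e-3)
  expect_equal(rep$curvature, "flat")
  expect_equal(classify_curvature(rep), "flat")
})

test_that("prescribed packing-angle differences are recovered within 1 degree", {
  for (delta in c(2, 5, 10)) {
    sol <- solenoid_with_curvature(delta, n_repeats = 4)
    expect_equal(sol$ground_truth$delta, delta, tolerance = 1e-6)
    rep <- packing_angles(sol$annotation, sol$structure)
    expect_lt(abs((rep$mean_BAB - rep$mean_ABA) - delta), 1)
    # delta = 2 sits exactly on the default flat band; beyond it the call is A
    if (delta > 2) expect_equal(rep$curvature, "toward-A")
  }
  neg <- make_solenoid(4, rotation_deg = -8)
  expect_lt(neg$ground_truth$delta, 0)
  expect_equal(packing_angles(neg$annotation, neg$structure)$curvature, "toward-B")
})

test_that("noisy solenoids still recover the ground-truth difference within 3 degrees", {
  for (seed in c(2, 9)) {
    sol <- make_solenoid(5, rotation_deg = 8, noise_sigma = 0.2, seed = seed)
    rep <- packing_angles(sol$annotation, sol$structure)
    expect_lt(abs((rep$mean_BAB - rep$mean_ABA) - sol$ground_truth$delta), 3)
  }
})

test_that("turn vectors follow the endpoint definition and alternate across the slab", {
  sol <- make_solenoid(3, rotation_deg = 0)
  ann <- sol$annotation
  s <- sol$structure
  tv <- turn_vector(ann[1, ], ann[2, ], s)
  ca <- function(res) as.numeric(s[s$resno == res & s$atom == "CA", c("x", "y", "z")])
  expect_equal(tv, ca(ann$start[2]) - ca(ann$end[1]), tolerance = 1e-12)
  # slab-normal (x) components alternate in sign along the solenoid
  signs <- sapply(seq_len(nrow(ann) - 1), function(i) {
    sign(turn_vector(ann[i, ], ann[i + 1, ], s)[1])
  })
  expect_true(all(signs == rep(c(-1, 1), length.out = length(signs))))
  expect_error(turn_vector(ann[2, ], ann[1, ], s), "not consecutive")
  missing_helix <- list(chain = "A", start = 9000L, end = 9010L)
  expect_error(turn_vector(ann[nrow(ann), ], missing_helix, s), "Missing CA")
})

test_that("packing angles are invariant under global rigid motion", {
  sol <- make_solenoid(4, rotation_deg = 6)
  base <- packing_angles(sol$annotation, sol$structure)$angles$angle
  for (seed in 1:3) {
    moved <- transform_coords(sol$structure, random_rotation(seed + 50), c(30, -12, 7))
    ang <- packing_angles(sol$annotation, moved)$angles$angle
    expect_lt(max(abs(ang - base)), 1e-3)
  }
})

test_that("annotation validation enforces alternation, order, and one chain", {
  good <- tibble::tibble(chain = "A", start = c(1, 20, 40), end = c(10, 30, 50),
                         face = c("A", "B", "A"))
  expect_s3_class(solenoid_annotation(good), "solenoid_annotation")
  bad_face <- good; bad_face$face <- c("B", "A", "B")
  expect_error(solenoid_annotation(bad_face), "alternate")
  bad_order <- good; bad_order$start[2] <- 5
  expect_error(solenoid_annotation(bad_order), "ascending")
  expect_error(packing_angles(solenoid_annotation(good[1:2, ]),
                              make_solenoid(2)$structure), ">= 3 helices")
})

test_that("local curvature reversals are flagged as anomalies", {
  # a toward-A solenoid in which one BAB angle drops below its flanking ABAs
  rows <- tibble::tibble(
    helix = 2:7,
    face = rep(c("B", "A"), 3),
    label = rep(c("ABA", "BAB"), 3),
    start = 1:6, end = 2:7,
    angle = c(144, 152, 145, 138, 143, 153),
    defined = TRUE
  )
  anom <- standscan:::find_anomalies(rows, "toward-A")
  expect_equal(anom, 5L) # the depressed BAB helix
  expect_length(standscan:::find_anomalies(rows, "flat"), 0)
})

test_that("turns parallel to the helix axis give undefined angles, excluded from means", {
  # Hand-built 7-helix stack. Helices use twist 90 deg over 9 residues, so
  # the 4-residue smoothing midpoints sit exactly on the axis and the fitted
  # axes are exact. The two turns bracketing helix 3 run exactly along its
  # axis (+z), so both projections vanish there; the B helices are tilted 5
  # degrees off antiparallel, so the same turns remain projectable at them.
  rx175 <- standscan:::rotation_about(c(1, 0, 0), 175)
  p0 <- c(2.3, 0, 0); p8 <- c(2.3, 0, 12)
  parts <- list(); starts <- ends <- numeric(0)
  last_ca <- NULL
  offsets <- list(NULL, c(4, 3, 1), c(0, 0, 5), c(0, 0, 5),
                  c(4, -3, 1), c(4, 3, 1), c(-4, 3, 1))
  for (k in 1:7) {
    rot <- if (k %% 2 == 1) diag(3) else rx175
    t_k <- if (k == 1) c(0, 0, 0) else (last_ca + offsets[[k]]) - as.numeric(rot %*% p0)
    h <- make_ideal_helix(9, twist = 90, start_resno = (k - 1) * 12 + 1,
                          rotation = rot, translation = t_k)
    parts[[k]] <- tibble::as_tibble(h)
    last_ca <- as.numeric(rot %*% p8) + t_k
    starts[k] <- (k - 1) * 12 + 1; ends[k] <- (k - 1) * 12 + 9
  }
  s <- as_structure(dplyr::bind_rows(parts), quiet = TRUE)
  ann <- solenoid_annotation(tibble::tibble(
    chain = "A", start = starts, end = ends,
    face = rep(c("A", "B"), length.out = 7)
  ))
  rep <- packing_angles(ann, s)
  expect_false(rep$angles$defined[rep$angles$helix == 3])
  expect_true(is.na(rep$angles$angle[rep$angles$helix == 3]))
  expect_true(all(rep$angles$defined[rep$angles$helix != 3]))
  expect_true(is.finite(rep$mean_ABA) && is.finite(rep$mean_BAB))
  expect_true(rep$curvature %in% c("toward-A", "toward-B", "flat"))
})

test_that("geometric helix detection segments synthetic solenoids", {
  sol <- make_solenoid(4, rotation_deg = 4)
  det <- detect_helices(sol$structure, "A")
  expect_equal(nrow(det), nrow(sol$annotation))
  # detected boundaries lie within a few residues of the construction
  expect_lt(max(abs(det$start - sol$annotation$start)), 6)
  expect_lt(max(abs(det$end - sol$annotation$end)), 6)
})

test_that("angle reports tidy, glance and plot", {
  sol <- make_solenoid(4, rotation_deg = 8)
  rep <- packing_angles(sol$annotation, sol$structure)
  td <- tidy(rep)
  expect_true(all(c("helix", "label", "angle", "anomaly") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$curvature, "toward-A")
  expect_s3_class(autoplot(rep), "ggplot")
})
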