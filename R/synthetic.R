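#' Build an ideal alpha-helix C-alpha trace
#'
#' C-alpha `i` (0-based) sits at
#' `placement %*% c(radius*cos(i*twist), radius*sin(i*twist), i*rise) + offset`,
#' i.e. an ideal helix wound about the local z axis, then rigidly placed.
#' Defaults are canonical alpha-helix parameters (rise 1.5 A/residue, twist
#' 100 deg/residue, C-alpha radius 2.3 A).
#'
#' @param n_residues Number of residues (>= 4).
#' @param rise Rise per residue, angstrom.
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, angstrom.
#' @param chain Chain id.
#' @param start_resno First author residue number.
#' @param rotation 3 x 3 placement rotation.
#' @param translation Length-3 placement offset, angstrom.
#' @return A `struct_tbl` C-alpha trace (residues `ALA`, atoms `CA`).
#' @export
make_ideal_helix <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3,
                             chain = "A", start_resno = 1L,
                             rotation = diag(3), translation = c(0, 0, 0)) {
  if (n_residues < 4) abort("A helix needs at least 4 residues")
  if (rise <= 0 || radius <= 0) abort("rise and radius must be > 0")
  i <- seq_len(n_residues) - 1
  tau <- twist * pi / 180
  xyz <- cbind(radius * cos(i * tau), radius * sin(i * tau), i * rise)
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  as_structure(
    tibble(
      chain = chain, resno = start_resno + i, resid = "ALA", atom = "CA",
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    ),
    id = "ideal_helix", quiet = TRUE
  )
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  k <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * k + (1 - ct) * tcrossprod(u)
}

# run code under a temporary RNG state; the caller's stream is untouched
with_local_seed <- function(seed, code) {
  if (is.null(seed)) abort("A seed is required")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a helical-hairpin solenoid with known ground-truth packing angles
#'
#' Stacks `n_repeats` antiparallel helical hairpins (an ascending A helix, a
#' turn, a descending B helix) into a TPR-like slab. Each successive repeat
#' is placed by one application of a screw transform: translation by
#' `stack` along the stacking direction plus rotation by `rotation_deg`
#' about an axis parallel to the helix axes through a point on the A side of
#' the slab. With `rotation_deg = 0` the repeats are related by pure
#' translation and the solenoid is a straight ladder (ground-truth ABA = BAB);
#' positive `rotation_deg` opens the turns on the A face so that BAB angles
#' exceed ABA angles — the canonical TPR curvature toward A — and negative
#' values curve the slab toward B.
#'
#' Ground-truth angles are computed from the construction frame — the exact
#' turn-endpoint coordinates and the exact (transform-propagated) helix axis
#' directions — before any noise is applied, independently of the
#' axis-fitting route used by [packing_angles()].
#'
#' @param n_repeats Number of hairpins (>= 2).
#' @param helix_len Residues per helix.
#' @param rise,twist,radius Ideal-helix parameters (see [make_ideal_helix()]).
#' @param pack_dist Distance between the A and B helix axes of a hairpin,
#'   angstrom.
#' @param stack Translation between successive repeats, angstrom.
#' @param turn_length Number of interpolated turn residues between helices.
#' @param rotation_deg Per-repeat rotation, degrees (sign as above).
#' @param rotation_center_x x offset of the screw axis; the default sits one
#'   stack spacing beyond the A face.
#' @param noise_sigma Isotropic Gaussian coordinate noise, angstrom.
#' @param seed RNG seed; required when `noise_sigma > 0`.
#' @param chain Chain id.
#' @return List with `structure` (a `struct_tbl`), `annotation` (a
#'   [solenoid_annotation()]), and `ground_truth` (list: per-helix `angles`
#'   tibble, `mean_ABA`, `mean_BAB`, `delta`).
#' @examples
#' sol <- make_solenoid(4, rotation_deg = 0)
#' sol$ground_truth$delta
#' @export
make_solenoid <- function(n_repeats = 4, helix_len = 12, rise = 1.5,
                          twist = 100, radius = 2.3, pack_dist = 10,
                          stack = 10, turn_length = 3, rotation_deg = 0,
                          rotation_center_x = NULL, noise_sigma = 0,
                          seed = NULL, chain = "A") {
  if (n_repeats < 2) abort("Need at least 2 repeats")
  if (noise_sigma > 0 && is.null(seed)) abort("seed is required when noise_sigma > 0")
  tau <- twist * pi / 180
  i <- seq_len(helix_len) - 1
  z_top <- (helix_len - 1) * rise
  # local hairpin: A winds up at x = +pack_dist/2, B winds down at -pack_dist/2
  a_local <- cbind(pack_dist / 2 + radius * cos(i * tau), radius * sin(i * tau), i * rise)
  b_local <- cbind(-pack_dist / 2 + radius * cos(i * tau), radius * sin(i * tau), z_top - i * rise)
  center_x <- rotation_center_x %||% (pack_dist / 2 + stack)
  rot <- rotation_about(c(0, 0, 1), rotation_deg)
  cen <- c(center_x, 0, 0)
  step <- function(p) sweep(sweep(p, 2, cen) %*% t(rot), 2, cen + c(0, stack, 0), "+")

  helices <- list() # coordinates per helix, in order A1 B1 A2 B2 ...
  axes <- list() # exact axis directions
  pa <- a_local; pb <- b_local
  da <- c(0, 0, 1); db <- c(0, 0, -1)
  for (k in seq_len(n_repeats)) {
    helices[[2 * k - 1]] <- pa
    helices[[2 * k]] <- pb
    axes[[2 * k - 1]] <- da
    axes[[2 * k]] <- db
    pa <- step(pa); pb <- step(pb)
    da <- as.numeric(rot %*% da); db <- as.numeric(rot %*% db)
  }

  # steric sanity across repeats
  for (k in seq_len(n_repeats - 1)) {
    x1 <- rbind(helices[[2 * k - 1]], helices[[2 * k]])
    x2 <- rbind(helices[[2 * k + 1]], helices[[2 * k + 2]])
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
    if (min(d2) < 1) abort("Repeat transform causes steric collapse (CA-CA < 1 A)")
  }

  # assemble residues: helix, turn, helix, turn, ...
  n_hel <- length(helices)
  rows <- list()
  ann <- list()
  resno <- 0L
  for (j in seq_len(n_hel)) {
    hxyz <- helices[[j]]
    ann[[j]] <- tibble(
      chain = chain, start = resno + 1L, end = resno + nrow(hxyz),
      face = if (j %% 2 == 1) "A" else "B"
    )
    rows[[length(rows) + 1]] <- tibble(
      chain = chain, resno = resno + seq_len(nrow(hxyz)), resid = "ALA",
      atom = "CA", element = "C",
      x = hxyz[, 1], y = hxyz[, 2], z = hxyz[, 3]
    )
    resno <- resno + nrow(hxyz)
    if (j < n_hel && turn_length > 0) {
      p0 <- helices[[j]][nrow(helices[[j]]), ]
      p1 <- helices[[j + 1]][1, ]
      f <- seq_len(turn_length) / (turn_length + 1)
      txyz <- outer(1 - f, p0) + outer(f, p1)
      rows[[length(rows) + 1]] <- tibble(
        chain = chain, resno = resno + seq_len(turn_length), resid = "GLY",
        atom = "CA", element = "C",
        x = txyz[, 1], y = txyz[, 2], z = txyz[, 3]
      )
      resno <- resno + turn_length
    }
  }
  ann <- dplyr::bind_rows(ann)
  annotation <- solenoid_annotation(ann)

  # ground truth from the construction frame (exact axes, exact endpoints)
  gt_rows <- purrr::map_dfr(2:(n_hel - 1), function(j) {
    t_in <- helices[[j]][1, ] - helices[[j - 1]][nrow(helices[[j - 1]]), ]
    t_out <- helices[[j + 1]][1, ] - helices[[j]][nrow(helices[[j]]), ]
    axis <- axes[[j]]
    tibble(
      helix = j,
      label = ifelse(j %% 2 == 1, "BAB", "ABA"),
      angle = angle_between_deg(project_perp(t_in, axis), project_perp(t_out, axis))
    )
  })
  gt <- list(
    angles = gt_rows,
    mean_ABA = mean(gt_rows$angle[gt_rows$label == "ABA"]),
    mean_BAB = mean(gt_rows$angle[gt_rows$label == "BAB"])
  )
  gt$delta <- gt$mean_BAB - gt$mean_ABA

  struct <- as_structure(dplyr::bind_rows(rows), id = "synthetic_solenoid", quiet = TRUE)
  if (noise_sigma > 0) struct <- perturb(struct, noise_sigma, seed)
  list(structure = struct, annotation = annotation, ground_truth = gt)
}

#' Build a solenoid with a prescribed ABA/BAB angle difference
#'
#' Solves (by root finding on the construction-frame ground truth) for the
#' per-repeat rotation that makes the ground-truth `mean_BAB - mean_ABA`
#' equal `delta_deg`, then builds that solenoid.
#'
#' @param delta_deg Target `mean_BAB - mean_ABA`, degrees (positive =
#'   curvature toward A).
#' @param ... Passed to [make_solenoid()] (everything except `rotation_deg`).
#' @return As [make_solenoid()].
#' @export
solenoid_with_curvature <- function(delta_deg, ...) {
  f <- function(rot) make_solenoid(rotation_deg = rot, ...)$ground_truth$delta - delta_deg
  sol <- stats::uniroot(f, interval = c(-25, 25), tol = 1e-8)
  make_solenoid(rotation_deg = sol$root, ...)
}

#' Add seeded Gaussian coordinate noise
#'
#' Independent, isotropic N(0, sigma^2) displacement of every atom;
#' reproducible under the given seed and leaving the caller's RNG stream
#' untouched. `sigma = 0` returns the input unchanged.
#'
#' @param structure A structure tibble.
#' @param sigma Standard deviation per coordinate, angstrom (>= 0).
#' @param seed RNG seed (required).
#' @return A perturbed `struct_tbl`.
#' @export
perturb <- function(structure, sigma, seed) {
  structure <- assert_structure(structure)
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(structure)
  n <- nrow(structure)
  noise <- with_local_seed(seed, matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3))
  structure$x <- structure$x + noise[, 1]
  structure$y <- structure$y + noise[, 2]
  structure$z <- structure$z + noise[, 3]
  structure
}

#' Random atom cloud for surface-area fixtures
#'
#' Uniformly seeded atom positions in a cube, with caller-assigned van der
#' Waals radii — the fixture of choice for exercising surface-area code
#' against closed-form and brute-force references.
#'
#' @param n Number of atoms (>= 1).
#' @param radii Van der Waals radii, recycled to `n`, angstrom.
#' @param box Cube edge, angstrom.
#' @param seed RNG seed (required).
#' @return A `struct_tbl` with one single-atom residue per sphere.
#' @export
make_sphere_cluster <- function(n, radii = 1.7, box = 10, seed) {
  if (n < 1) abort("n must be >= 1")
  xyz <- with_local_seed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
  r <- rep_len(radii, n)
  as_structure(
    tibble(
      chain = "A", resno = seq_len(n), resid = "SPH", atom = "X",
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = r
    ),
    id = "sphere_cluster", quiet = TRUE
  )
}
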