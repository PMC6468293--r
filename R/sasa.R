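#' Deterministic Fibonacci sphere lattice
#'
#' `n` near-uniform unit-sphere directions from the golden-angle spiral with
#' the standard half-step offset; fully deterministic, so every
#' surface-area result is bit-reproducible.
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# All pairs (i from A, j from B) with distance < cutoff, via a uniform cell
# grid (cell edge = cutoff, 27-cell neighborhoods). Output is identical to
# the all-pairs computation, in arbitrary order.
grid_pairs <- function(xa, xb, cutoff) {
  stopifnot(cutoff > 0)
  key <- function(x) {
    c0 <- floor(sweep(x, 2, c(0, 0, 0)) / cutoff)
    paste(c0[, 1], c0[, 2], c0[, 3])
  }
  ka <- key(xa)
  index_a <- split(seq_len(nrow(xa)), ka)
  cell_b <- split(seq_len(nrow(xb)), key(xb))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (ck in names(cell_b)) {
    jb <- cell_b[[ck]]
    c0 <- as.integer(strsplit(ck, " ")[[1]])
    cand <- unlist(index_a[paste(c0[1] + offs[, 1], c0[2] + offs[, 2], c0[3] + offs[, 3])],
                   use.names = FALSE)
    if (length(cand) == 0) next
    d2 <- outer(rowSums(xb[jb, , drop = FALSE]^2), rowSums(xa[cand, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xb[jb, , drop = FALSE], xa[cand, , drop = FALSE])
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out_i <- c(out_i, cand[hit[, 2]])
      out_j <- c(out_j, jb[hit[, 1]])
      out_d <- c(out_d, sqrt(pmax(0, d2[hit])))
    }
  }
  list(i = out_i, j = out_j, d = out_d)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the atom spheres by sampling `n_points`
#' Fibonacci-lattice directions on each atom's expanded sphere (radius
#' `vdw + probe`) and counting the sample points not buried inside any
#' neighbour's expanded sphere:
#' `area_i = exposed_i / n_points * 4 * pi * (r_i + probe)^2`.
#'
#' @param atoms A structure tibble (or any data frame with `x`, `y`, `z`,
#'   `vdw`); at least one atom, finite coordinates.
#' @param probe Probe radius, angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample count (>= 16; default 960).
#' @return A `sasa_result`: list with `per_atom` (input columns plus `area`
#'   in square angstrom), `total`, `probe`, `n_points`.
#' @examples
#' s <- make_sphere_cluster(5, seed = 1)
#' glance(shrake_rupley(s))
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960) {
  atoms <- assert_structure(atoms)
  if (nrow(atoms) < 1) abort("Need at least one atom")
  if (probe < 0) abort("probe must be >= 0")
  if (n_points < 16) abort("n_points must be >= 16")
  xyz <- coords_matrix(atoms)
  if (!all(is.finite(xyz))) abort("Non-finite coordinates")
  r <- atoms$vdw + probe
  n <- nrow(xyz)
  sph <- fibonacci_sphere(n_points)

  # neighbour lists: pairs with d < r_i + r_j
  nb <- vector("list", n)
  if (n > 1) {
    pr <- grid_pairs(xyz, xyz, 2 * max(r))
    keep <- pr$i != pr$j & pr$d < r[pr$i] + r[pr$j]
    if (any(keep)) {
      nb <- split(pr$i[keep], factor(pr$j[keep], levels = seq_len(n)))
    }
  }

  area <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (is.null(js) || length(js) == 0) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- sweep(sph * r[i], 2, xyz[i, ], "+")
    nxyz <- xyz[js, , drop = FALSE]
    d2 <- outer(rowSums(pts^2), rowSums(nxyz^2), "+") - 2 * tcrossprod(pts, nxyz)
    buried <- d2 < matrix(r[js]^2, nrow = n_points, ncol = length(js), byrow = TRUE)
    exposed <- sum(rowSums(buried) == 0)
    area[i] <- exposed / n_points * 4 * pi * r[i]^2
  }
  per_atom <- mutate(as_tibble(atoms), area = area)
  structure(
    list(per_atom = per_atom, total = sum(area), probe = probe, n_points = n_points),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "<sasa_result: %.2f A^2 over %d atoms (probe %.2f A, %d points)>\n",
    x$total, nrow(x$per_atom), x$probe, x$n_points
  ))
  invisible(x)
}

#' @rdname shrake_rupley
#' @param x A `sasa_result`.
#' @param ... Unused.
#' @export
tidy.sasa_result <- function(x, ...) {
  select(x$per_atom, all_of(c("chain", "resno", "resid", "atom", "area")))
}

#' @rdname shrake_rupley
#' @export
glance.sasa_result <- function(x, ...) {
  tibble(total = x$total, n_atoms = nrow(x$per_atom), probe = x$probe, n_points = x$n_points)
}

resolve_disjoint_pair <- function(structure, sel_a, sel_b) {
  a <- select_atoms(structure, sel_a)
  b <- select_atoms(structure, sel_b)
  if (nrow(a) == 0) abort("Selection A resolves to no atoms")
  if (nrow(b) == 0) abort("Selection B resolves to no atoms")
  key <- function(s) paste(s$chain, s$resno, s$ins, s$atom)
  if (length(intersect(key(a), key(b))) > 0) {
    abort("Selections overlap at the atom level")
  }
  list(a = a, b = b)
}

#' Buried interface area between two selections
#'
#' The buried area is `(SASA_A + SASA_B - SASA_AB) / 2` — the per-side
#' average of the solvent-accessible area each partner loses on complex
#' formation, clamped at zero. By default the two selections are extracted
#' from the structure and treated as an isolated pair (pairwise
#' accounting); `context = "full-structure"` instead measures the loss of
#' accessible area within the whole structure when the partner is removed.
#'
#' @param structure A structure tibble.
#' @param sel_a,sel_b Disjoint [atom_selection()]s (hetero atoms excluded by
#'   the default selections).
#' @param probe Probe radius, angstrom.
#' @param n_points Sphere samples per atom.
#' @param context `"isolated-pair"` (default) or `"full-structure"`.
#' @return Buried area in square angstrom (length-1 numeric).
#' @seealso [shrake_rupley()], [find_contacts()]
#' @export
buried_interface_area <- function(structure, sel_a, sel_b, probe = 1.4,
                                  n_points = 960,
                                  context = c("isolated-pair", "full-structure")) {
  context <- match.arg(context)
  structure <- assert_structure(structure)
  pair <- resolve_disjoint_pair(structure, sel_a, sel_b)
  a <- pair$a; b <- pair$b
  if (context == "isolated-pair") {
    sa <- shrake_rupley(a, probe, n_points)$total
    sb <- shrake_rupley(b, probe, n_points)$total
    ab <- as_structure(dplyr::bind_rows(as_tibble(a), as_tibble(b)), quiet = TRUE)
    sab <- shrake_rupley(ab, probe, n_points)$total
    return(max(0, (sa + sb - sab) / 2))
  }
  key <- function(s) paste(s$chain, s$resno, s$ins, s$atom)
  full <- filter(as_tibble(structure), !.data$is_hetero)
  full <- as_structure(full, quiet = TRUE)
  kf <- key(full); ka <- key(a); kb <- key(b)
  area_of <- function(ctx, sel_keys) {
    res <- shrake_rupley(ctx, probe, n_points)$per_atom
    sum(res$area[key(res) %in% sel_keys])
  }
  no_b <- as_structure(full[!(kf %in% kb), ], quiet = TRUE)
  no_a <- as_structure(full[!(kf %in% ka), ], quiet = TRUE)
  lost_a <- area_of(no_b, ka) - area_of(full, ka)
  lost_b <- area_of(no_a, kb) - area_of(full, kb)
  max(0, (lost_a + lost_b) / 2)
}

#' Residue contacts between two selections
#'
#' Residue pairs whose minimum heavy-atom distance is within `cutoff`;
#' classed `hbond` when the closest nitrogen/oxygen-to-nitrogen/oxygen
#' distance is within 3.5 angstrom (donor/acceptor chemistry is deliberately
#' not inferred — low-resolution structures deposit no hydrogens), `vdw`
#' otherwise. Grid-accelerated, with output identical to the all-pairs
#' computation, sorted by residue.
#'
#' @param structure A structure tibble.
#' @param sel_a,sel_b Non-empty [atom_selection()]s.
#' @param cutoff Heavy-atom contact cutoff, angstrom (default 4.0).
#' @param hbond_cutoff N/O-N/O distance, angstrom, below which a contact is
#'   classed `hbond` (default 3.5).
#' @return Tibble: `chain_a`, `resno_a`, `resid_a`, `chain_b`, `resno_b`,
#'   `resid_b`, `min_dist`, `class`.
#' @export
find_contacts <- function(structure, sel_a, sel_b, cutoff = 4.0,
                          hbond_cutoff = 3.5) {
  structure <- assert_structure(structure)
  a <- select_atoms(structure, sel_a)
  b <- select_atoms(structure, sel_b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("Both selections must resolve to atoms")
  pr <- grid_pairs(coords_matrix(a), coords_matrix(b), cutoff + 1e-6)
  keep <- pr$d <= cutoff
  pr <- list(i = pr$i[keep], j = pr$j[keep], d = pr$d[keep])
  if (length(pr$i) == 0) {
    return(tibble(
      chain_a = character(), resno_a = integer(), resid_a = character(),
      chain_b = character(), resno_b = integer(), resid_b = character(),
      min_dist = double(), class = character()
    ))
  }
  hits <- tibble(
    chain_a = a$chain[pr$i], resno_a = a$resno[pr$i], resid_a = a$resid[pr$i],
    el_a = a$element[pr$i],
    chain_b = b$chain[pr$j], resno_b = b$resno[pr$j], resid_b = b$resid[pr$j],
    el_b = b$element[pr$j],
    d = pr$d
  )
  hits |>
    group_by(.data$chain_a, .data$resno_a, .data$resid_a,
             .data$chain_b, .data$resno_b, .data$resid_b) |>
    summarise(
      min_dist = min(.data$d),
      no_min = {
        is_no <- .data$el_a %in% c("N", "O") & .data$el_b %in% c("N", "O")
        if (any(is_no)) min(.data$d[is_no]) else Inf
      },
      .groups = "drop"
    ) |>
    mutate(class = ifelse(.data$no_min <= hbond_cutoff, "hbond", "vdw")) |>
    select(-"no_min") |>
    arrange(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b)
}
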