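#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' least-squares deviation of `R %*% mobile + t` from `reference`, via the
#' SVD of the coordinate cross-covariance with the usual reflection
#' correction, and reports the post-fit RMSD.
#'
#' @param mobile,reference N x 3 coordinate matrices (angstrom), paired
#'   row-by-row; N >= 3 and not all collinear.
#' @return A `superposition` object with elements `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (angstrom) and `n_atoms`. The rotation
#'   convention is `fitted = mobile %*% t(rotation) + translation`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(x, x)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3) abort("Coordinates must be N x 3")
  n <- nrow(mobile)
  if (n != nrow(reference)) abort("mobile and reference must pair row-by-row")
  if (n < 3) abort("Need at least 3 paired atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- crossprod(a, b) # 3x3 covariance
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    abort("Degenerate (collinear or coincident) coordinates: superposition undefined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u) # reference = rot %*% mobile
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  structure(
    list(
      rotation = rot,
      translation = as.numeric(cr - rot %*% cm),
      rmsd = rmsd,
      n_atoms = n
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition: rmsd %.4f A over %d atoms>\n", x$rmsd, x$n_atoms
  ))
  invisible(x)
}

#' Apply a superposition (or any rigid transform) to coordinates
#'
#' @param coords N x 3 matrix, or a structure tibble.
#' @param rotation 3 x 3 proper rotation.
#' @param translation Length-3 vector.
#' @return Object of the same kind with transformed coordinates.
#' @export
transform_coords <- function(coords, rotation, translation = c(0, 0, 0)) {
  if (is_structure(coords) || is.data.frame(coords)) {
    s <- assert_structure(coords)
    xyz <- coords_matrix(s) %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, "+")
    s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
    return(s)
  }
  sweep(as.matrix(coords) %*% t(rotation), 2, translation, "+")
}

#' Pair atoms of two chains by author numbering
#'
#' Matches atoms between two chains by (author residue number, insertion
#' code, atom name); unmatched residues are dropped and pairs come back in
#' ascending residue order.
#'
#' @param struct_a,struct_b Structure tibbles.
#' @param chain_a,chain_b Chain ids within each.
#' @param atom_name Atom to pair on (default `"CA"`).
#' @return List with `a`, `b` (paired N x 3 coordinate matrices) and `resno`
#'   (the common author numbers).
#' @export
map_common_atoms <- function(struct_a, chain_a, struct_b, chain_b,
                             atom_name = "CA") {
  xa <- select_atoms(struct_a, atom_selection(chain = chain_a, atoms = atom_name))
  xb <- select_atoms(struct_b, atom_selection(chain = chain_b, atoms = atom_name))
  key_a <- paste(xa$resno, xa$ins)
  key_b <- paste(xb$resno, xb$ins)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) {
    abort(paste0(
      "Chains ", chain_a, " and ", chain_b, " share no '", atom_name, "' atoms"
    ))
  }
  xa <- xa[match(common, key_a), ]
  xb <- xb[match(common, key_b), ]
  ord <- order(xa$resno, xa$ins)
  xa <- xa[ord, ]; xb <- xb[ord, ]
  list(a = coords_matrix(xa), b = coords_matrix(xb), resno = xa$resno)
}

#' All pairwise chain superpositions of a structure
#'
#' Superposes every unordered pair of polymer chains over their common
#' C-alpha set — the standard check that copies in an asymmetric unit are
#' conformationally identical.
#'
#' @param structure A structure tibble.
#' @param atom_name Atom used for pairing (default `"CA"`).
#' @return Tibble with `chain_a`, `chain_b`, `n_atoms`, `rmsd` (angstrom).
#' @export
superpose_all_chains <- function(structure, atom_name = "CA") {
  structure <- assert_structure(structure)
  chains <- unique(filter(as_tibble(structure), !.data$is_hetero)$chain)
  if (length(chains) < 2) abort("Need at least two polymer chains")
  pairs <- utils::combn(chains, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    m <- map_common_atoms(structure, pairs[1, k], structure, pairs[2, k], atom_name)
    fit <- kabsch_superpose(m$a, m$b)
    tibble(
      chain_a = pairs[1, k], chain_b = pairs[2, k],
      n_atoms = fit$n_atoms, rmsd = fit$rmsd
    )
  })
}

#' @rdname kabsch_superpose
#' @param x A `superposition` object.
#' @param ... Unused.
#' @export
tidy.superposition <- function(x, ...) {
  tibble(
    axis = c("x", "y", "z"),
    r1 = x$rotation[, 1], r2 = x$rotation[, 2], r3 = x$rotation[, 3],
    translation = x$translation
  )
}

#' @rdname kabsch_superpose
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms, det = det(x$rotation))
}
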