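#' Residue-pair distances
#'
#' Euclidean distances between chosen atoms of residue pairs — the geometry
#' behind engineered-cysteine cross-linking: two residues whose C-beta atoms
#' lie within disulfide reach can be cross-linked when both are mutated to
#' cysteine. `atom = "CB"` falls back to C-alpha for glycine (or any residue
#' lacking a C-beta), recorded per pair in `note`; `"closest-heavy"` uses the
#' minimum over all heavy-atom pairs.
#'
#' @param structure A structure tibble.
#' @param pairs Data frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`.
#' @param atom `"CB"` (default), `"CA"`, or `"closest-heavy"`.
#' @return A `distance_report` tibble: the input pairs plus `distance`
#'   (angstrom), `atom_a`, `atom_b`, `note`.
#' @seealso [disulfide_feasibility()], [patch_span()]
#' @export
pair_distances <- function(structure, pairs, atom = c("CB", "CA", "closest-heavy")) {
  structure <- assert_structure(structure)
  atom <- match.arg(atom)
  pairs <- as_tibble(pairs)
  need <- c("chain_a", "resno_a", "chain_b", "resno_b")
  if (!all(need %in% names(pairs))) {
    abort(paste0("pairs needs columns ", paste(need, collapse = ", ")))
  }
  res_atoms <- function(chain, resno) {
    a <- select_atoms(structure, atom_selection(
      chain = chain, residues = resno, hetero = "include"
    ))
    if (nrow(a) == 0) {
      abort(paste0("Cannot resolve residue ", chain, ":", resno))
    }
    a
  }
  out <- purrr::pmap_dfr(pairs, function(chain_a, resno_a, chain_b, resno_b, ...) {
    ra <- res_atoms(chain_a, resno_a)
    rb <- res_atoms(chain_b, resno_b)
    if (atom == "closest-heavy") {
      d2 <- outer(rowSums(coords_matrix(ra)^2), rowSums(coords_matrix(rb)^2), "+") -
        2 * tcrossprod(coords_matrix(ra), coords_matrix(rb))
      k <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      return(tibble(
        chain_a = chain_a, resno_a = resno_a, chain_b = chain_b, resno_b = resno_b,
        distance = sqrt(max(0, min(d2))),
        atom_a = ra$atom[k[1]], atom_b = rb$atom[k[2]], note = ""
      ))
    }
    pick <- function(r, chain, resno) {
      hit <- r[r$atom == atom, ]
      if (nrow(hit) > 0) return(list(a = hit[1, ], note = ""))
      if (atom == "CB") {
        ca <- r[r$atom == "CA", ]
        if (nrow(ca) > 0) {
          return(list(a = ca[1, ], note = paste0(chain, ":", resno, " CB->CA fallback")))
        }
      }
      abort(paste0("Residue ", chain, ":", resno, " has no ", atom, " atom"))
    }
    pa <- pick(ra, chain_a, resno_a)
    pb <- pick(rb, chain_b, resno_b)
    dv <- as.numeric(pa$a[, c("x", "y", "z")]) - as.numeric(pb$a[, c("x", "y", "z")])
    tibble(
      chain_a = chain_a, resno_a = resno_a, chain_b = chain_b, resno_b = resno_b,
      distance = sqrt(sum(dv^2)),
      atom_a = pa$a$atom, atom_b = pb$a$atom,
      note = trimws(paste(pa$note, pb$note))
    )
  })
  base::structure(out, class = c("distance_report", class(tibble())))
}

#' Disulfide cross-link feasibility
#'
#' Flags residue pairs whose (C-beta) distance permits an engineered
#' cysteine pair to form a disulfide. The default threshold of 7 angstrom is
#' a deliberately permissive cross-linking tolerance: catalyzed oxidation of
#' flexible surface side chains traps transient proximity well beyond the
#' ~4-6 angstrom of an ideal S-S geometry. Feasibility is monotone in the
#' threshold by construction.
#'
#' @param report A `distance_report` from [pair_distances()].
#' @param threshold Feasibility threshold, angstrom.
#' @return The report with `feasible` and `threshold` columns; class
#'   preserved.
#' @export
disulfide_feasibility <- function(report, threshold = 7.0) {
  if (!"distance" %in% names(report)) abort("Expected a distance_report")
  out <- mutate(as_tibble(report), feasible = .data$distance <= threshold,
                threshold = threshold)
  structure(out, class = c("distance_report", class(tibble())))
}

#' Span of distances between two surface patches
#'
#' Exact minimum and maximum over all inter-patch atom-pair distances. Patch
#' membership must be given explicitly (residue lists in the selections);
#' nothing is inferred.
#'
#' @param structure A structure tibble.
#' @param patch_a,patch_b Non-empty [atom_selection()]s.
#' @return One-row tibble: `min_dist`, `max_dist` (angstrom), `n_pairs`.
#' @export
patch_span <- function(structure, patch_a, patch_b) {
  structure <- assert_structure(structure)
  a <- select_atoms(structure, patch_a)
  b <- select_atoms(structure, patch_b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("Both patches must resolve to atoms")
  xa <- coords_matrix(a); xb <- coords_matrix(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2 <- pmax(d2, 0)
  tibble(
    min_dist = sqrt(min(d2)), max_dist = sqrt(max(d2)),
    n_pairs = length(d2)
  )
}
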