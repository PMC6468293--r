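#' Fit the axis of an alpha-helix from its C-alpha trace
#'
#' Smooths the trace with sliding 4-residue midpoints (window 3 for very
#' short helices) and takes the principal axis of the centered midpoints,
#' oriented N-to-C. This is robust for the short (10-15 residue) helices of
#' TPR solenoids, where fitting raw C-alpha positions would be dominated by
#' the helical wind itself.
#'
#' @param ca M x 3 matrix of consecutive C-alpha coordinates, M >= 4.
#' @return List with `point` (centroid of the smoothed trace) and
#'   `direction` (unit vector, N-terminal to C-terminal).
#' @examples
#' h <- make_ideal_helix(12)
#' fit_helix_axis(coords_matrix(h))$direction
#' @export
fit_helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  m <- nrow(ca)
  if (m < 4) abort("Need at least 4 C-alpha atoms to fit a helix axis")
  w <- if (m >= 5) 4L else 3L
  k <- m - w + 1
  mid <- vapply(seq_len(k), function(i) colMeans(ca[i:(i + w - 1), , drop = FALSE]),
                numeric(3))
  mid <- t(mid)
  center <- colMeans(mid)
  dev <- sweep(mid, 2, center)
  if (max(abs(dev)) < 1e-9) {
    abort("Degenerate helix: smoothed trace collapses to a point")
  }
  sv <- svd(dev)
  dir <- sv$v[, 1]
  # orient N -> C
  if (sum((mid[k, ] - mid[1, ]) * dir) < 0) dir <- -dir
  list(point = center, direction = dir / sqrt(sum(dir^2)))
}

#' Define a solenoid annotation
#'
#' An annotation is an ordered table of helix segments with strictly
#' alternating face labels, `A` first: in a TPR-like solenoid the first
#' helices of the hairpins build the A face and the second helices the B
#' face. Segments must be ascending and non-overlapping along the chain.
#'
#' @param helices Data frame with columns `chain`, `start`, `end`, `face`
#'   (`"A"`/`"B"`), in N-to-C order.
#' @return A `solenoid_annotation` tibble.
#' @export
solenoid_annotation <- function(helices) {
  h <- as_tibble(helices)
  need <- c("chain", "start", "end", "face")
  if (!all(need %in% names(h))) {
    abort("Annotation needs columns chain, start, end, face")
  }
  if (nrow(h) < 1) abort("Annotation has no helices")
  expected <- rep(c("A", "B"), length.out = nrow(h))
  if (!identical(as.character(h$face), expected)) {
    abort("Face labels must strictly alternate A, B, A, ... starting at A")
  }
  if (any(h$start > h$end)) abort("Helix start > end")
  if (nrow(h) > 1) {
    if (any(h$start[-1] <= h$end[-nrow(h)])) {
      abort("Helix segments must be ascending and non-overlapping")
    }
    if (length(unique(h$chain)) != 1) abort("All helices must be on one chain")
  }
  structure(h, class = c("solenoid_annotation", class(tibble())))
}

helix_ca <- function(structure, chain, start, end) {
  sel <- select_atoms(structure, atom_selection(chain = chain, range = c(start, end), atoms = "CA"))
  if (nrow(sel) == 0) {
    abort(paste0("No CA atoms for helix ", chain, ":", start, "-", end))
  }
  sel
}

#' Turn vector between two consecutive helices
#'
#' The direction of the inter-helix turn, taken as the vector from the
#' C-alpha of the last residue of the preceding helix to the C-alpha of the
#' first residue of the following helix.
#'
#' @param prev_helix,next_helix One-row data frames (or lists) with `chain`,
#'   `start`, `end`; `next_helix` must follow `prev_helix` on the same chain.
#' @param structure A structure tibble.
#' @return Length-3 numeric vector (angstrom).
#' @export
turn_vector <- function(prev_helix, next_helix, structure) {
  if (prev_helix$chain != next_helix$chain) abort("Helices are on different chains")
  if (next_helix$start <= prev_helix$end) abort("Helices are not consecutive in sequence")
  ca_of <- function(chain, resno) {
    a <- select_atoms(structure, atom_selection(chain = chain, residues = resno, atoms = "CA"))
    if (nrow(a) == 0) {
      abort(paste0("Missing CA for residue ", chain, ":", resno, " (turn endpoint)"))
    }
    as.numeric(a[1, c("x", "y", "z")])
  }
  ca_of(next_helix$chain, next_helix$start) - ca_of(prev_helix$chain, prev_helix$end)
}

project_perp <- function(v, axis) {
  v - sum(v * axis) * axis
}

angle_between_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  cosang <- sum(u * v) / (cu * cv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Turn-packing angles of a helical solenoid (ABA/BAB statistic)
#'
#' For every interior helix, the two turns that bracket it are projected
#' onto the plane perpendicular to the helix's fitted axis, and the unsigned
#' angle between the projections is recorded: at an A helix this is a BAB
#' angle, at a B helix an ABA angle. In a canonically curved TPR solenoid
#' the BAB angles exceed the ABA angles and the slab bends toward the A
#' face; the reverse ordering bends it toward B. Interior helices whose own
#' angle ordering (relative to their flanking opposite-label angles)
#' contradicts the global call are flagged as anomalies — local reversals of
#' this kind mark changes in curvature along a solenoid.
#'
#' @param solenoid A [solenoid_annotation()] with at least 3 helices.
#' @param structure A structure tibble containing the annotated chain.
#' @param flat_band Half-width (degrees) of the mean-difference band called
#'   `flat` (default 2, below the fitting noise of short noisy helices).
#' @return An `angle_report`: list with `angles` (tibble: `helix`, `face`,
#'   `label`, `start`, `end`, `angle`, `defined`), `mean_ABA`, `mean_BAB`,
#'   `curvature` (`"toward-A"`, `"toward-B"` or `"flat"`), and `anomalies`
#'   (interior-helix indices).
#' @seealso [classify_curvature()], [make_solenoid()]
#' @export
packing_angles <- function(solenoid, structure, flat_band = 2) {
  h <- as_tibble(solenoid)
  if (nrow(h) < 3) abort("Need >= 3 helices so at least one interior helix exists")
  structure <- assert_structure(structure)
  n <- nrow(h)
  rows <- purrr::map_dfr(2:(n - 1), function(i) {
    ca <- coords_matrix(helix_ca(structure, h$chain[i], h$start[i], h$end[i]))
    axis <- fit_helix_axis(ca)$direction
    t_in <- turn_vector(h[i - 1, ], h[i, ], structure)
    t_out <- turn_vector(h[i, ], h[i + 1, ], structure)
    p_in <- project_perp(t_in, axis)
    p_out <- project_perp(t_out, axis)
    ok <- sqrt(sum(p_in^2)) >= 1e-3 * sqrt(sum(t_in^2)) &&
      sqrt(sum(p_out^2)) >= 1e-3 * sqrt(sum(t_out^2))
    tibble(
      helix = i, face = h$face[i],
      label = ifelse(h$face[i] == "A", "BAB", "ABA"),
      start = h$start[i], end = h$end[i],
      angle = if (ok) angle_between_deg(p_in, p_out) else NA_real_,
      defined = ok
    )
  })
  mean_aba <- mean(rows$angle[rows$label == "ABA" & rows$defined])
  mean_bab <- mean(rows$angle[rows$label == "BAB" & rows$defined])
  rep <- base::structure(
    list(
      angles = rows, mean_ABA = mean_aba, mean_BAB = mean_bab,
      flat_band = flat_band, curvature = NA_character_,
      anomalies = integer(0), chain = h$chain[1]
    ),
    class = "angle_report"
  )
  if (is.finite(mean_aba) && is.finite(mean_bab)) {
    rep$curvature <- classify_curvature(rep)
    rep$anomalies <- find_anomalies(rows, rep$curvature)
  } else {
    warn("Too few defined packing angles to call curvature")
  }
  rep
}

#' Classify solenoid curvature from an angle report
#'
#' `toward-A` when the mean BAB angle exceeds the mean ABA angle by more
#' than the flat band, `toward-B` for the reverse, `flat` in between.
#'
#' @param report An `angle_report` from [packing_angles()].
#' @param flat_band Band half-width in degrees; defaults to the one recorded
#'   in the report.
#' @return `"toward-A"`, `"toward-B"` or `"flat"`.
#' @export
classify_curvature <- function(report, flat_band = NULL) {
  flat_band <- flat_band %||% report$flat_band %||% 2
  if (!is.finite(report$mean_ABA) || !is.finite(report$mean_BAB)) {
    abort("Need at least one valid ABA and one valid BAB angle")
  }
  delta <- report$mean_BAB - report$mean_ABA
  if (delta > flat_band) "toward-A" else if (delta < -flat_band) "toward-B" else "flat"
}

# Interior helices whose local angle ordering opposes the global curvature
# call. The local reference for a helix is the mean of the defined angles of
# its flanking interior helices (which carry the opposite label).
find_anomalies <- function(rows, curvature) {
  if (curvature == "flat") return(integer(0))
  sgn <- if (curvature == "toward-A") 1 else -1 # expected sign of BAB - ABA
  out <- integer(0)
  for (k in seq_len(nrow(rows))) {
    if (!rows$defined[k]) next
    nb <- rows[abs(rows$helix - rows$helix[k]) == 1 & rows$defined, ]
    if (nrow(nb) == 0) next
    local_ref <- mean(nb$angle)
    contrast <- if (rows$label[k] == "BAB") rows$angle[k] - local_ref else local_ref - rows$angle[k]
    if (sgn * contrast < 0) out <- c(out, rows$helix[k])
  }
  out
}

#' @export
print.angle_report <- function(x, ...) {
  cat(sprintf(
    "<angle_report: %d interior helices, mean ABA %.2f deg, mean BAB %.2f deg, curvature %s%s>\n",
    nrow(x$angles), x$mean_ABA, x$mean_BAB, x$curvature,
    if (length(x$anomalies) > 0) {
      paste0(", anomalies at helix ", paste(x$anomalies, collapse = ","))
    } else ""
  ))
  print(x$angles)
  invisible(x)
}

#' @rdname packing_angles
#' @param x An `angle_report`.
#' @param ... Unused.
#' @export
tidy.angle_report <- function(x, ...) {
  mutate(x$angles, anomaly = .data$helix %in% x$anomalies)
}

#' @rdname packing_angles
#' @export
glance.angle_report <- function(x, ...) {
  tibble(
    mean_ABA = x$mean_ABA, mean_BAB = x$mean_BAB,
    delta = x$mean_BAB - x$mean_ABA,
    curvature = x$curvature, n_anomalies = length(x$anomalies)
  )
}

#' Geometric helix detection on a C-alpha trace
#'
#' A fallback segmenter for synthetic traces (real structures should use
#' curated helix tables). A residue window is called helical when the
#' three-residue chord `|CA_i - CA_(i+3)|` is short (about 5 angstrom in an
#' alpha-helix, versus ~11 angstrom for an extended stretch); maximal runs of
#' at least `min_len` residues become helices, labelled A/B alternately from
#' the first.
#'
#' @param structure A structure tibble (C-alpha trace).
#' @param chain Chain id.
#' @param min_len Minimum run length in residues.
#' @param chord_max Maximum `i` to `i+3` chord length, angstrom.
#' @return A [solenoid_annotation()].
#' @export
detect_helices <- function(structure, chain, min_len = 5, chord_max = 6.5) {
  ca <- select_atoms(structure, atom_selection(chain = chain, atoms = "CA"))
  ca <- arrange(as_tibble(ca), .data$resno)
  xyz <- cbind(ca$x, ca$y, ca$z)
  m <- nrow(xyz)
  if (m < min_len + 3) abort("Trace too short for helix detection")
  k <- m - 3
  chord <- sqrt(rowSums((xyz[seq_len(k) + 3, , drop = FALSE] -
                           xyz[seq_len(k), , drop = FALSE])^2))
  helical <- chord <= chord_max
  runs <- rle(helical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segs <- tibble(
    s = starts[runs$values], e = ends[runs$values]
  ) |>
    # chord index i covers residues i..i+3
    mutate(res_start = ca$resno[.data$s], res_end = ca$resno[pmin(.data$e + 3, m)])
  # clip overlaps introduced by the window extension
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      segs$res_start[i] <- max(segs$res_start[i], segs$res_end[i - 1] + 1L)
    }
  }
  segs <- filter(segs, .data$res_end - .data$res_start + 1 >= min_len)
  if (nrow(segs) == 0) abort("No helical segments detected")
  solenoid_annotation(tibble(
    chain = chain, start = segs$res_start, end = segs$res_end,
    face = rep(c("A", "B"), length.out = nrow(segs))
  ))
}
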