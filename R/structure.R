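#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate arrange group_by ungroup summarise select
#'   distinct left_join bind_rows n row_number across all_of
#' @importFrom tibble tibble as_tibble
NULL

# Bondi-style van der Waals radii (angstrom). Elements outside the table get
# the carbon radius with a warning at load time.
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
.vdw_default <- 1.70

#' Van der Waals radius lookup
#'
#' Maps element symbols to Bondi-style van der Waals radii. Unknown elements
#' receive the default carbon-like radius of 1.70 angstrom with a warning.
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"N"`).
#' @param quiet Suppress the unknown-element warning.
#' @return Numeric vector of radii in angstrom.
#' @examples
#' vdw_radius(c("C", "O", "Zn"), quiet = TRUE)
#' @export
vdw_radius <- function(element, quiet = FALSE) {
  element <- toupper(trimws(as.character(element)))
  r <- unname(.vdw_table[element])
  unknown <- is.na(r) & !is.na(element) & nzchar(element)
  if (any(unknown) && !quiet) {
    warn(paste0(
      "Unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
      "; using default vdW radius ", .vdw_default, " A"
    ))
  }
  r[is.na(r)] <- .vdw_default
  r
}

#' Build a structure tibble from atom records
#'
#' A structure is a tibble with one row per atom and the columns
#' `chain`, `resno` (author residue number), `ins` (insertion code, `""` when
#' absent), `resid` (3-letter residue name), `atom` (atom name), `element`,
#' `x`, `y`, `z` (angstrom), `occ`, `b`, `is_hetero`, and `vdw` (angstrom).
#' The crystallographic cell, if any, travels in the `cell` attribute and the
#' identifier in the `id` attribute.
#'
#' @param atoms Data frame with at least `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z`. Missing `ins`, `occ`, `b`, `is_hetero` are
#'   filled with defaults; `vdw` is assigned from [vdw_radius()].
#' @param id Structure identifier.
#' @param cell Optional cell: list with `a`, `b`, `c`, `alpha`, `beta`,
#'   `gamma` and optionally `space_group`.
#' @param quiet Suppress unknown-element warnings.
#' @return A `struct_tbl` (tibble subclass).
#' @examples
#' as_structure(data.frame(
#'   chain = "A", resno = 1, resid = "ALA", atom = "CA",
#'   element = "C", x = 0, y = 0, z = 0
#' ))
#' @export
as_structure <- function(atoms, id = "structure", cell = NULL, quiet = FALSE) {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("Atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Non-finite coordinates in atom table")
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"is_hetero" %in% names(atoms)) atoms$is_hetero <- FALSE
  if (!"vdw" %in% names(atoms)) atoms$vdw <- vdw_radius(atoms$element, quiet = quiet)
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)) {
    abort("Occupancies must lie in [0, 1]")
  }
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, c(
    "chain", "resno", "ins", "resid", "atom", "element",
    "x", "y", "z", "occ", "b", "is_hetero", "vdw",
    setdiff(names(atoms), c(
      "chain", "resno", "ins", "resid", "atom", "element",
      "x", "y", "z", "occ", "b", "is_hetero", "vdw"
    ))
  )]
  if (!is.null(cell)) cell <- validate_cell(cell)
  structure(
    atoms,
    id = id, cell = cell,
    class = c("struct_tbl", class(tibble()))
  )
}

validate_cell <- function(cell) {
  need <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (!all(need %in% names(cell))) {
    abort("Cell needs a, b, c, alpha, beta, gamma")
  }
  lens <- unlist(cell[c("a", "b", "c")])
  if (any(!is.finite(lens)) || any(lens <= 0)) abort("Cell lengths must be > 0")
  cell[c(need, intersect("space_group", names(cell)))]
}

is_structure <- function(x) inherits(x, "struct_tbl")

assert_structure <- function(x) {
  if (!is_structure(x)) {
    if (is.data.frame(x)) return(as_structure(x, quiet = TRUE))
    abort("Expected a struct_tbl (see as_structure())")
  }
  x
}

#' @export
print.struct_tbl <- function(x, ...) {
  cl <- attr(x, "cell")
  chains <- unique(x$chain)
  cat(
    "# structure '", attr(x, "id") %||% "?", "': ",
    nrow(x), " atoms, ",
    nrow(distinct(as_tibble(x), .data$chain, .data$resno, .data$ins, .data$is_hetero)),
    " residues, chains [", paste(chains, collapse = " "), "]\n",
    sep = ""
  )
  if (!is.null(cl)) {
    cat(sprintf(
      "# cell: a=%.2f b=%.2f c=%.2f alpha=%.1f beta=%.1f gamma=%.1f %s\n",
      cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma, cl$space_group %||% ""
    ))
  }
  NextMethod()
}

# Subsetting a struct_tbl keeps its class and attributes.
#' @export
`[.struct_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("chain", "resno", "atom", "x", "y", "z") %in% names(out))) {
    attr(out, "id") <- attr(x, "id")
    attr(out, "cell") <- attr(x, "cell")
    class(out) <- c("struct_tbl", class(tibble()))
  }
  out
}

restore_struct <- function(out, template) {
  attr(out, "id") <- attr(template, "id")
  attr(out, "cell") <- attr(template, "cell")
  class(out) <- c("struct_tbl", class(tibble()))
  out
}

#' Per-chain residue and atom census
#'
#' @param structure A structure tibble.
#' @param polymer_only Count only non-hetero residues.
#' @return Tibble with `chain`, `n_residues`, `n_atoms`.
#' @export
chain_census <- function(structure, polymer_only = TRUE) {
  structure <- assert_structure(structure)
  tab <- as_tibble(structure)
  if (polymer_only) tab <- filter(tab, !.data$is_hetero)
  tab |>
    group_by(.data$chain) |>
    summarise(
      n_residues = dplyr::n_distinct(paste(.data$resno, .data$ins)),
      n_atoms = n(),
      .groups = "drop"
    )
}

#' Hetero (ligand) residues of a structure
#'
#' @param structure A structure tibble.
#' @return Tibble with one row per hetero residue: `chain`, `resno`, `resid`,
#'   `n_atoms`.
#' @export
ligand_residues <- function(structure) {
  structure <- assert_structure(structure)
  as_tibble(structure) |>
    filter(.data$is_hetero) |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(n_atoms = n(), .groups = "drop")
}

#' Coordinates of an atom table as an N x 3 matrix
#'
#' @param atoms A structure tibble or any data frame with `x`, `y`, `z`.
#' @return N x 3 numeric matrix (angstrom).
#' @export
coords_matrix <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}
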