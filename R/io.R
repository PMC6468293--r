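#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses atom records with `bio3d`, resolves alternate locations by keeping
#' the highest-occupancy conformer (ties broken alphabetically by altloc id),
#' assigns van der Waals radii from the element, and captures the
#' crystallographic cell and space group when the file carries them. Author
#' residue numbering is preserved throughout — this is the numbering used in
#' all downstream selections.
#'
#' @param path File path.
#' @param format `"pdb"`, `"cif"` (mmCIF), or `"auto"` (from the extension).
#' @param keep_waters Retain water (`HOH`/`WAT`/`DOD`) residues. Default drops
#'   them; crystallographic waters are irrelevant to every analysis here.
#' @param keep_hydrogens Retain hydrogens. Default drops them (a 3.4-angstrom
#'   structure deposits none, and all geometry here is heavy-atom based).
#' @param quiet Suppress unknown-element warnings.
#' @return A `struct_tbl`; hetero residues are flagged via `is_hetero`, the
#'   cell (if any) is in `attr(, "cell")`.
#' @seealso [write_structure()], [select_atoms()], [get_cell()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_waters = FALSE, keep_hydrogens = FALSE,
                           quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      cif = "cif", mmcif = "cif",
      pdb = "pdb", ent = "pdb",
      abort(paste0("Cannot infer format from extension '.", ext, "'; pass format="))
    )
  }
  parsed <- tryCatch(
    if (format == "cif") {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE))
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE)
    },
    error = function(e) {
      abort(paste0("Failed to parse ", path, " as ", format, ": ", conditionMessage(e)))
    }
  )
  at <- as_tibble(parsed$atom)
  if (nrow(at) == 0) abort(paste0("No atom records in ", path))

  atoms <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    atom = as.character(at$elety),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    element = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    is_hetero = at$type == "HETATM"
  )
  atoms <- resolve_altlocs(atoms)
  if (!keep_hydrogens) atoms <- filter(atoms, !(.data$element %in% c("H", "D")))
  if (!keep_waters) atoms <- filter(atoms, !(.data$resid %in% c("HOH", "WAT", "DOD")))
  if (nrow(atoms) == 0) abort(paste0("No atoms left after filtering in ", path))

  cell <- if (format == "pdb") parse_cell_pdb(path) else parse_cell_cif(path)
  id <- tools::file_path_sans_ext(basename(path))
  if (format == "cif") {
    # keep the data block name so write-read-write is byte-stable
    blk <- grep("^data_", readLines(path, n = 20, warn = FALSE), value = TRUE)
    if (length(blk) > 0) id <- sub("^data_", "", blk[[1]])
  }
  as_structure(select(atoms, -"alt"), id = id, cell = cell, quiet = quiet)
}

# Highest occupancy wins; ties break alphabetically by altloc id.
resolve_altlocs <- function(atoms) {
  atoms |>
    group_by(.data$chain, .data$resno, .data$ins, .data$resid, .data$atom) |>
    arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$ins)
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(as.character(elesy)))
  miss <- is.na(el) | !nzchar(el)
  if (any(miss)) {
    # fall back on the first alphabetic character of the atom name
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']*", "", as.character(elety[miss])))
    el[miss] <- toupper(substr(nm, 1, 1))
  }
  el
}

parse_cell_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) == 0) return(NULL)
  cr <- cr[[1]]
  vals <- suppressWarnings(as.numeric(c(
    substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
    substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54)
  )))
  if (any(is.na(vals))) return(NULL)
  # PDB writers emit a placeholder unit cell for non-crystallographic models
  if (all(vals == c(1, 1, 1, 90, 90, 90))) return(NULL)
  list(
    a = vals[1], b = vals[2], c = vals[3],
    alpha = vals[4], beta = vals[5], gamma = vals[6],
    space_group = trimws(substr(cr, 56, 66))
  )
}

parse_cell_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[[1]]), "\\s+")[[1]][2]))
  }
  a <- grab("_cell.length_a"); b <- grab("_cell.length_b"); cc <- grab("_cell.length_c")
  al <- grab("_cell.angle_alpha"); be <- grab("_cell.angle_beta"); ga <- grab("_cell.angle_gamma")
  if (any(is.na(c(a, b, cc, al, be, ga)))) return(NULL)
  sg <- grep("^_symmetry.space_group_name_H-M\\s", lines, value = TRUE)
  sg <- if (length(sg) > 0) {
    gsub("^['\"]|['\"]$", "", trimws(sub("^\\S+\\s+", "", trimws(sg[[1]]))))
  } else {
    NULL
  }
  c(list(a = a, b = b, c = cc, alpha = al, beta = be, gamma = ga),
    if (!is.null(sg)) list(space_group = sg))
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output uses fixed columns (coordinates at 3 decimals) and is refused
#' for structures that overflow them (>= 100000 atoms or author residue
#' numbers outside \[-999, 9999\]); mmCIF has no such limits. Both outputs
#' re-read identically with [read_structure()] at serialization precision.
#'
#' @param structure A structure tibble.
#' @param path Output path.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "cif")) {
  structure <- assert_structure(structure)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      cif = "cif", mmcif = "cif", pdb = "pdb",
      abort(paste0("Cannot infer format from extension '.", ext, "'; pass format="))
    )
  }
  if (nrow(structure) == 0) abort("Refusing to write an empty structure")
  if (format == "pdb") {
    if (nrow(structure) >= 1e5 || any(structure$resno > 9999 | structure$resno < -999)) {
      abort("Structure exceeds PDB fixed-column limits; write mmCIF instead")
    }
    write_pdb_file(structure, path)
  } else {
    write_cif_file(structure, path)
  }
  invisible(path)
}

write_pdb_file <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- attr(s, "cell")
  if (!is.null(cl)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
      cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma, cl$space_group %||% "P 1"
    ), con)
  }
  rec <- ifelse(s$is_hetero, "HETATM", "ATOM  ")
  # atom-name column convention: names of <4 chars start in column 14
  nm <- ifelse(
    nchar(s$atom) >= 4,
    sprintf("%-4s", s$atom),
    sprintf(" %-3s", s$atom)
  )
  writeLines(sprintf(
    "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
    rec, seq_len(nrow(s)) %% 100000, nm, s$resid, s$chain, s$resno,
    ifelse(nzchar(s$ins), s$ins, " "),
    s$x, s$y, s$z, s$occ, s$b, s$element
  ), con)
  writeLines("END", con)
}

write_cif_file <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  id <- gsub("\\s", "_", attr(s, "id") %||% "structure")
  writeLines(paste0("data_", id), con)
  cl <- attr(s, "cell")
  if (!is.null(cl)) {
    writeLines(sprintf("_cell.length_a     %.3f", cl$a), con)
    writeLines(sprintf("_cell.length_b     %.3f", cl$b), con)
    writeLines(sprintf("_cell.length_c     %.3f", cl$c), con)
    writeLines(sprintf("_cell.angle_alpha  %.2f", cl$alpha), con)
    writeLines(sprintf("_cell.angle_beta   %.2f", cl$beta), con)
    writeLines(sprintf("_cell.angle_gamma  %.2f", cl$gamma), con)
    if (!is.null(cl$space_group)) {
      writeLines(sprintf("_symmetry.space_group_name_H-M \"%s\"", cl$space_group), con)
    }
  }
  writeLines(c(
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  ), con)
  writeLines(sprintf(
    "%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    ifelse(s$is_hetero, "HETATM", "ATOM"), seq_len(nrow(s)), s$element,
    s$atom, s$resid, s$chain, s$resno,
    ifelse(nzchar(s$ins), s$ins, "?"),
    s$x, s$y, s$z, s$occ, s$b, s$resno, s$resid, s$chain, s$atom
  ), con)
}

#' Crystallographic cell parameters
#'
#' @param structure A structure tibble.
#' @return A tibble with one row (`a`, `b`, `c`, `alpha`, `beta`, `gamma`,
#'   `space_group`) or, when the structure carries no cell, a zero-row tibble
#'   with the same columns. Absence is a value, not an error.
#' @export
get_cell <- function(structure) {
  structure <- assert_structure(structure)
  cl <- attr(structure, "cell")
  if (is.null(cl)) {
    return(tibble(
      a = double(), b = double(), c = double(),
      alpha = double(), beta = double(), gamma = double(),
      space_group = character()
    ))
  }
  tibble(
    a = cl$a, b = cl$b, c = cl$c,
    alpha = cl$alpha, beta = cl$beta, gamma = cl$gamma,
    space_group = cl$space_group %||% NA_character_
  )
}

#' Read a domain map / solenoid / analysis configuration block
#'
#' Domain maps are YAML (or JSON) lists of entries with keys `name`, `chain`,
#' `start`, `end` and optionally `atoms`. Overlapping ranges on the same
#' chain are allowed but flagged with a warning, since domain boundaries are
#' annotations, not partitions.
#'
#' @param path YAML or JSON file.
#' @return Tibble with columns `name`, `chain`, `start`, `end`, `atoms`
#'   (list-column, `NULL` = all atom names).
#' @export
read_domain_map <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- if (!is.null(raw$domains)) raw$domains else raw
  out <- purrr::map_dfr(entries, function(e) {
    tibble(
      name = as.character(e$name), chain = as.character(e$chain),
      start = as.integer(e$start), end = as.integer(e$end),
      atoms = list(if (is.null(e$atoms)) NULL else as.character(e$atoms))
    )
  })
  if (any(out$start > out$end)) abort("Domain map has start > end")
  if (anyDuplicated(paste(out$chain, out$name))) {
    abort("Domain names must be unique per chain")
  }
  flag_overlaps(out)
  out
}

flag_overlaps <- function(map) {
  by_chain <- split(map, map$chain)
  for (m in by_chain) {
    if (nrow(m) < 2) next
    for (i in seq_len(nrow(m) - 1)) {
      for (j in seq(i + 1, nrow(m))) {
        if (m$start[i] <= m$end[j] && m$start[j] <= m$end[i]) {
          warn(paste0(
            "Domain ranges overlap on chain ", m$chain[i], ": ",
            m$name[i], " and ", m$name[j]
          ))
        }
      }
    }
  }
  invisible(map)
}
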