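#' Read an analysis configuration
#'
#' A YAML file describing a complete resting-form analysis: domain
#' boundaries, interface pairs, ligand selector, solenoid helix tables,
#' residue pairs and patches, and numeric overrides. See
#' `system.file("extdata", "ph0952.yaml", package = "standscan")` for the
#' bundled example encoding the PH0952 domain architecture.
#'
#' @param path YAML file.
#' @return A list of class `analysis_config` (the parsed YAML, with the raw
#'   text attached for provenance echoing).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "raw") <- paste(readLines(path, warn = FALSE), collapse = "\n")
  class(cfg) <- "analysis_config"
  cfg
}

config_domains <- function(cfg) {
  purrr::map_dfr(cfg$domains, function(d) {
    tibble(
      name = as.character(d$name), chain = as.character(d$chain),
      start = as.integer(d$start), end = as.integer(d$end)
    )
  })
}

domain_selection <- function(domains, name, chain = NULL, atoms = NULL) {
  hit <- domains[domains$name == name & (is.null(chain) | domains$chain == (chain %||% domains$chain)), ]
  if (nrow(hit) == 0) abort(paste0("Unknown domain '", name, "'"))
  atom_selection(chain = hit$chain[1], range = c(hit$start[1], hit$end[1]), atoms = atoms)
}

validate_config <- function(structure, cfg) {
  errs <- character(0)
  chains <- unique(structure$chain)
  domains <- config_domains(cfg)
  for (k in seq_len(nrow(domains))) {
    if (!domains$chain[k] %in% chains) {
      errs <- c(errs, paste0("domain ", domains$name[k], ": no chain ", domains$chain[k]))
    } else if (nrow(select_atoms(structure, atom_selection(
      chain = domains$chain[k], range = c(domains$start[k], domains$end[k])
    ))) == 0) {
      errs <- c(errs, paste0("domain ", domains$name[k], ": empty range"))
    }
  }
  for (pair in cfg$interfaces %||% list()) {
    parts <- strsplit(pair, ":")[[1]]
    for (p in parts) {
      if (!p %in% domains$name) errs <- c(errs, paste0("interface ", pair, ": unknown domain ", p))
    }
  }
  for (sol in cfg$solenoids %||% list()) {
    for (h in sol$helices) {
      if (!h$chain %in% chains) {
        errs <- c(errs, paste0("solenoid ", sol$name, ": no chain ", h$chain))
      }
    }
  }
  for (p in cfg$pairs %||% list()) {
    for (side in c("a", "b")) {
      ch <- p[[paste0("chain_", side)]]
      if (!is.null(ch) && !ch %in% chains) {
        errs <- c(errs, paste0("pair: no chain ", ch))
      }
    }
  }
  if (length(errs) > 0) {
    abort(paste0("Invalid configuration:\n  - ", paste(errs, collapse = "\n  - ")))
  }
  invisible(TRUE)
}

#' Run the full resting-form structural analysis
#'
#' Executes, in fixed order, every stage requested by the configuration:
#' chain census and cell bookkeeping, all pairwise chain superpositions,
#' domain-pair buried-interface areas with contacts, ligand-pocket contact
#' mapping, per-solenoid packing-angle reports with curvature calls, and
#' residue-pair distance / patch-span analyses. The configuration is
#' validated in full (aggregated errors) before anything is computed, and is
#' echoed into the report for provenance; re-running on identical inputs
#' reproduces the report exactly.
#'
#' @param structure A structure tibble (or a path, read via
#'   [read_structure()]).
#' @param config An `analysis_config` (or a path, read via
#'   [read_analysis_config()]).
#' @return An `analysis_report`: named list of tibbles (`census`, `cell`,
#'   `superpositions`, `interfaces`, `contacts`, `pocket`, `solenoids`,
#'   `solenoid_angles`, `distances`, `spans`) plus the config echo.
#' @export
analyze <- function(structure, config) {
  if (is.character(structure)) structure <- read_structure(structure)
  structure <- assert_structure(structure)
  if (is.character(config)) config <- read_analysis_config(config)
  validate_config(structure, config)
  domains <- config_domains(config)
  probe <- config$probe %||% 1.4
  n_points <- config$n_points %||% 960
  cutoff <- config$cutoff %||% 4.0

  census <- chain_census(structure)
  ligands <- ligand_residues(structure)
  cell <- get_cell(structure)

  n_chains <- length(unique(filter(as_tibble(structure), !.data$is_hetero)$chain))
  superpositions <- if (n_chains >= 2) superpose_all_chains(structure) else {
    tibble(chain_a = character(), chain_b = character(), n_atoms = integer(), rmsd = double())
  }

  interfaces <- purrr::map_dfr(config$interfaces %||% list(), function(pair) {
    parts <- strsplit(pair, ":")[[1]]
    sa <- domain_selection(domains, parts[1])
    sb <- domain_selection(domains, parts[2])
    tibble(
      pair = pair,
      buried_area = buried_interface_area(structure, sa, sb, probe = probe, n_points = n_points)
    )
  })
  contacts <- purrr::map_dfr(config$interfaces %||% list(), function(pair) {
    parts <- strsplit(pair, ":")[[1]]
    mutate(
      find_contacts(structure, domain_selection(domains, parts[1]),
                    domain_selection(domains, parts[2]), cutoff = cutoff),
      pair = pair
    )
  })

  pocket <- if (!is.null(config$ligand)) {
    lig_sel <- atom_selection(
      chain = config$ligand$chain %||% NULL, hetero = "only"
    )
    lig <- select_atoms(structure, lig_sel)
    lig <- lig[lig$resid == (config$ligand$resid %||% "ADP"), ]
    if (nrow(lig) == 0) {
      tibble(chain_a = character(), resno_a = integer(), resid_a = character(),
             chain_b = character(), resno_b = integer(), resid_b = character(),
             min_dist = double(), class = character())
    } else {
      prot_sel <- atom_selection(chain = config$ligand$chain %||% NULL, hetero = "exclude")
      lig_only <- atom_selection(
        chain = config$ligand$chain %||% NULL,
        residues = unique(lig$resno), hetero = "only"
      )
      find_contacts(structure, lig_only, prot_sel,
                    cutoff = config$ligand$cutoff %||% 4.0)
    }
  } else NULL

  sol_results <- purrr::map(config$solenoids %||% list(), function(sol) {
    ann <- solenoid_annotation(purrr::map_dfr(sol$helices, as_tibble))
    rep <- packing_angles(ann, structure)
    list(name = sol$name, report = rep)
  })
  solenoids <- purrr::map_dfr(sol_results, function(s) {
    mutate(glance(s$report), name = s$name,
           anomalies = paste(s$report$anomalies, collapse = ","))
  })
  solenoid_angles <- purrr::map_dfr(sol_results, function(s) {
    mutate(tidy(s$report), name = s$name)
  })

  distances <- if (!is.null(config$pairs)) {
    rep <- pair_distances(structure, purrr::map_dfr(config$pairs, as_tibble),
                          atom = config$atom %||% "CB")
    as_tibble(disulfide_feasibility(rep, threshold = config$threshold %||% 7.0))
  } else NULL

  spans <- purrr::map_dfr(config$spans %||% list(), function(sp) {
    mk <- function(side) {
      atom_selection(chain = sp[[side]]$chain,
                     residues = unlist(sp[[side]]$residues),
                     hetero = "include")
    }
    mutate(patch_span(structure, mk("patch_a"), mk("patch_b")), name = sp$name)
  })

  base::structure(
    list(
      id = attr(structure, "id"),
      census = census, ligands = ligands, cell = cell,
      superpositions = superpositions, interfaces = interfaces,
      contacts = contacts, pocket = pocket,
      solenoids = solenoids, solenoid_angles = solenoid_angles,
      distances = distances, spans = spans,
      config = attr(config, "raw") %||% ""
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report '", x$id, "'>\n", sep = "")
  cat("  chains:", nrow(x$census), " interfaces:", nrow(x$interfaces),
      " solenoids:", nrow(x$solenoids), "\n")
  invisible(x)
}

#' Write an analysis report as JSON (and optional TSV sections)
#'
#' JSON output is deterministic — identical inputs yield byte-identical
#' files (no timestamps, fixed numeric formatting).
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @param tsv_dir Optional directory for one TSV per tabular section.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tsv_dir = NULL) {
  payload <- report[!vapply(report, is.null, logical(1))]
  class(payload) <- NULL
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = 6, pretty = TRUE)
  if (!is.null(tsv_dir)) {
    dir.create(tsv_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(payload)) {
      if (is.data.frame(payload[[nm]]) && nrow(payload[[nm]]) > 0) {
        utils::write.table(payload[[nm]], file.path(tsv_dir, paste0(nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(path)
}
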