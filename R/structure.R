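#' Residue names treated as nucleic acid
#'
#' Default residue-name alphabet used to recognize nucleic-acid chains
#' (rRNA, tRNA, mRNA, DNA). A chain is classified nucleic when more than
#' half of its residues carry one of these names.
#'
#' @return Character vector of residue names.
#' @export
nucleic_residue_names <- function() {
  c("A", "U", "G", "C", "I", "N",
    "DA", "DT", "DG", "DC", "DI", "DU", "DN",
    "1MA", "5MC", "7MG", "PSU", "H2U", "OMC", "OMG", "M2G", "YG")
}

#' Load and clean a complex structure
#'
#' Reads a PDB or mmCIF file, removes hetero atoms (HETATM records),
#' resolves duplicate atoms, excludes nucleic-acid chains, and annotates
#' the remaining protein chains with names and subunit labels from a
#' chain-annotation table.
#'
#' Duplicate resolution: within each (chain, residue, atom name) group that
#' carries alternate locations, the highest-occupancy conformer is kept,
#' with ties broken by the alphabetically first altloc code; exact
#' duplicates keep their first occurrence.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param annotation A chain-annotation tibble (see [read_chain_annotation()])
#'   or path to one. Every annotated chain must exist in the file; chains
#'   present in the file but not annotated are excluded.
#' @param keep_nucleic Keep nucleic chains instead of moving them to the
#'   excluded list (default `FALSE`).
#' @param nucleic_residues Residue-name alphabet for nucleic detection.
#' @param structure_id Identifier stamped on the structure; defaults to the
#'   lower-cased file base name.
#' @return An object of class `complex_structure`: a list with tibbles
#'   `atoms` (retained, annotated atoms), `chains` (one row per retained
#'   chain), `excluded` (excluded entities and why), plus bookkeeping
#'   counts `n_atoms_input`, `n_hetero_removed`, `n_duplicates_removed`.
#' @export
load_structure <- function(path, annotation, keep_nucleic = FALSE,
                           nucleic_residues = nucleic_residue_names(),
                           structure_id = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop_structenrich(
      paste0("structure file is missing or empty: ", path),
      "structenrich_format_error"
    )
  }
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- read_chain_annotation(annotation)
  }
  annotation <- as_chain_annotation(annotation)

  atoms <- read_structure_atoms(path)
  if (nrow(atoms) == 0) {
    stop_structenrich(paste0("no atom records in ", path),
                      "structenrich_format_error")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_structenrich("non-finite atom coordinates",
                      "structenrich_format_error")
  }

  unknown <- setdiff(annotation$chain_id, unique(atoms$chain_id))
  if (length(unknown) > 0) {
    stop_structenrich(
      paste0("annotation references chain(s) absent from the structure: ",
             paste(unknown, collapse = ", ")),
      "structenrich_annotation_error"
    )
  }

  n_input <- nrow(atoms)
  n_hetero <- sum(atoms$is_hetero)
  atoms <- filter(atoms, !.data$is_hetero)

  # altloc / duplicate-atom resolution (keep best conformer per atom)
  n_before <- nrow(atoms)
  atoms <- atoms %>%
    mutate(.ord = row_number(),
           .occ = ifelse(is.na(.data$occupancy), 1, .data$occupancy),
           .alt = ifelse(is.na(.data$altloc), "", .data$altloc)) %>%
    group_by(.data$chain_id, .data$residue_id, .data$atom_name) %>%
    arrange(desc(.data$.occ), .data$.alt, .data$.ord, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-all_of(c(".ord", ".occ", ".alt")))
  n_dup <- n_before - nrow(atoms)

  # nucleic chain detection on distinct residues
  chain_class <- atoms %>%
    distinct(.data$chain_id, .data$residue_id, .data$residue_name) %>%
    group_by(.data$chain_id) %>%
    summarise(frac_nuc = mean(.data$residue_name %in% nucleic_residues),
              .groups = "drop") %>%
    mutate(nucleic = .data$frac_nuc > 0.5)

  excluded <- tibble(chain_id = character(), reason = character())
  if (!keep_nucleic) {
    nuc <- chain_class$chain_id[chain_class$nucleic]
    nuc <- setdiff(nuc, character())
    # annotated chains are never auto-excluded as nucleic
    nuc <- setdiff(nuc, annotation$chain_id)
    if (length(nuc) > 0) {
      excluded <- bind_rows(excluded,
                            tibble(chain_id = nuc, reason = "nucleic"))
      atoms <- filter(atoms, !.data$chain_id %in% nuc)
    }
  }
  unannotated <- setdiff(unique(atoms$chain_id), annotation$chain_id)
  if (length(unannotated) > 0) {
    excluded <- bind_rows(excluded,
                          tibble(chain_id = unannotated,
                                 reason = "unannotated"))
    atoms <- filter(atoms, .data$chain_id %in% annotation$chain_id)
  }
  if (nrow(atoms) == 0) {
    stop_structenrich("no protein chains retained after cleaning",
                      "structenrich_empty_structure_error")
  }

  atoms <- atoms %>%
    left_join(select(annotation, all_of(c("chain_id", "protein_name",
                                          "subunit"))),
              by = "chain_id")

  chains <- atoms %>%
    group_by(.data$chain_id, .data$protein_name, .data$subunit) %>%
    summarise(n_residues = dplyr::n_distinct(.data$residue_id),
              n_atoms = n(), .groups = "drop") %>%
    arrange(.data$chain_id)
  dup_names <- chains$protein_name[duplicated(chains$protein_name)]
  if (length(dup_names) > 0) {
    rlang::warn(paste0(
      "protein_name shared by multiple chains (merged into one network ",
      "node downstream): ", paste(unique(dup_names), collapse = ", ")))
  }

  if (is.null(structure_id)) {
    structure_id <- tolower(sub("\\.(pdb|cif|ent)$", "",
                                basename(path), ignore.case = TRUE))
  }
  structure_id <- gsub("[^a-z0-9]", "", tolower(structure_id))

  structure(
    list(
      structure_id = structure_id,
      atoms = atoms,
      chains = chains,
      excluded = excluded,
      residues = NULL,
      centroid_mode = NULL,
      n_atoms_input = n_input,
      n_hetero_removed = n_hetero,
      n_duplicates_removed = n_dup
    ),
    class = "complex_structure"
  )
}

# Parse a PDB or mmCIF file into an atom tibble via bio3d.
read_structure_atoms <- function(path) {
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    {
      if (ext == "cif") {
        bio3d::read.cif(path, verbose = FALSE)
      } else {
        bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE,
                        verbose = FALSE)
      }
    },
    error = function(e) {
      stop_structenrich(
        paste0("could not parse structure file ", path, ": ",
               conditionMessage(e)),
        "structenrich_format_error"
      )
    }
  )
  at <- parsed$atom
  tibble(
    chain_id = as.character(at$chain),
    residue_number = at$resno,
    residue_id = paste0(at$resno, ifelse(is.na(at$insert), "", at$insert)),
    residue_name = as.character(at$resid),
    atom_name = as.character(at$elety),
    element = as.character(at$elesy),
    altloc = as.character(at$alt),
    occupancy = at$o,
    x = at$x, y = at$y, z = at$z,
    is_hetero = at$type == "HETATM"
  )
}

#' Coarse-grain residues to their centers of gravity
#'
#' Collapses every residue to a single point: by default the unweighted
#' arithmetic mean of its retained atom coordinates (geometric centroid);
#' optionally a mass-weighted center using standard atomic masses.
#'
#' @param structure A `complex_structure`.
#' @param mode `"geometric"` (default) or `"mass"`.
#' @return The structure with a `residues` tibble (`chain_id`,
#'   `protein_name`, `subunit`, `residue_id`, `x`, `y`, `z`, `n_atoms`);
#'   residue count is unchanged by this operation.
#' @export
compute_centroids <- function(structure, mode = c("geometric", "mass")) {
  stopifnot(inherits(structure, "complex_structure"))
  mode <- match.arg(mode)
  atoms <- structure$atoms
  if (nrow(atoms) == 0) {
    stop_structenrich("structure has no atoms", "structenrich_data_error")
  }
  w <- if (mode == "mass") {
    env <- new.env()
    utils::data("elements", package = "bio3d", envir = env)
    ele <- suppressWarnings(bio3d::atom2ele(atoms$atom_name,
                                            rescue = TRUE))
    m <- env$elements$mass[match(ele, env$elements$symb)]
    ifelse(is.na(m), 12, m)  # unknown elements fall back to carbon
  } else {
    rep(1, nrow(atoms))
  }
  atoms$.w <- w
  res <- atoms %>%
    group_by(.data$chain_id, .data$protein_name, .data$subunit,
             .data$residue_id) %>%
    summarise(
      x = sum(.data$x * .data$.w) / sum(.data$.w),
      y = sum(.data$y * .data$.w) / sum(.data$.w),
      z = sum(.data$z * .data$.w) / sum(.data$.w),
      n_atoms = n(),
      .groups = "drop"
    )
  if (any(res$n_atoms < 1)) {
    bad <- res %>% filter(.data$n_atoms < 1)
    stop_structenrich(
      paste0("residue(s) without atoms: ",
             paste(bad$chain_id, bad$residue_id, collapse = ", ")),
      "structenrich_data_error"
    )
  }
  structure$atoms$.w <- NULL
  structure$residues <- res
  structure$centroid_mode <- mode
  structure
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure>", x$structure_id, "\n")
  cat("  chains:", nrow(x$chains),
      "| atoms retained:", nrow(x$atoms),
      "| hetero removed:", x$n_hetero_removed,
      "| duplicates removed:", x$n_duplicates_removed, "\n")
  cat("  excluded entities:", nrow(x$excluded), "\n")
  if (!is.null(x$residues)) {
    cat("  residue centroids:", nrow(x$residues),
        sprintf("(%s)", x$centroid_mode), "\n")
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.complex_structure <- function(x, ...) {
  if (is.null(x$residues)) x$atoms else x$residues
}

#' Write a cleaned-structure summary TSV
#'
#' One row per retained chain: chain id, protein name, subunit, residue
#' count.
#'
#' @param structure A `complex_structure`.
#' @param path Output path.
#' @param header Extra `# `-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_structure_summary <- function(structure, path, header = character()) {
  stopifnot(inherits(structure, "complex_structure"))
  df <- structure$chains %>%
    select(all_of(c("chain_id", "protein_name", "subunit", "n_residues")))
  write_tsv_with_header(df, path,
                        c(paste0("structure_id=", structure$structure_id),
                          header))
}
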