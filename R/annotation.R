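#' Read a chain annotation table
#'
#' A chain annotation maps the chain identifiers of a structure file to
#' protein names in the universal ribosomal protein nomenclature (uL/eL for
#' the large subunit, uS/eS for the small subunit) and to a subunit label.
#' It replaces sequence-based (BLAST) verification with an explicit,
#' user-curated lookup.
#'
#' @param path Path to a TSV file with columns `chain_id`, `protein_name`,
#'   `subunit` and optionally `paralog_ids` (comma-separated).
#' @return A tibble with columns `chain_id`, `protein_name`, `subunit` and a
#'   list-column `paralog_ids`.
#' @export
read_chain_annotation <- function(path) {
  ann <- read_tsv_skip_comments(path)
  as_chain_annotation(ann)
}

#' Validate a data frame as a chain annotation
#'
#' @param ann A data frame with columns `chain_id`, `protein_name`,
#'   `subunit` and optionally `paralog_ids`.
#' @return A normalized annotation tibble.
#' @export
as_chain_annotation <- function(ann) {
  needed <- c("chain_id", "protein_name", "subunit")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols) > 0) {
    stop_structenrich(
      paste0("annotation is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "structenrich_annotation_error"
    )
  }
  ann <- as_tibble(ann)
  if (anyDuplicated(ann$chain_id)) {
    stop_structenrich("annotation has duplicated chain_id entries",
                      "structenrich_annotation_error")
  }
  if (!"paralog_ids" %in% names(ann)) ann$paralog_ids <- NA_character_
  ann %>%
    mutate(
      chain_id = as.character(.data$chain_id),
      protein_name = as.character(.data$protein_name),
      subunit = as.character(.data$subunit),
      paralog_ids = purrr::map(.data$paralog_ids, function(x) {
        x <- as.character(unlist(x))
        x <- x[!is.na(x) & nzchar(x)]
        if (length(x) == 0) character() else
          unlist(stringr::str_split(x, ",\\s*"))
      })
    ) %>%
    select(all_of(c("chain_id", "protein_name", "subunit", "paralog_ids")))
}

#' Universal ribosomal protein family names
#'
#' The accepted family names of the universal (uL/eL/uS/eS) ribosomal
#' protein nomenclature for cytosolic 80S ribosomes, plus the P-stalk
#' proteins (P1, P2) and RACK1. Used by [validate_annotation()].
#'
#' @return A character vector of family names.
#' @export
rp_nomenclature <- function() {
  c(
    # large subunit, universal
    paste0("uL", c(1:6, 10, 11, 13:16, 18, 22:24, 29, 30)),
    # large subunit, eukaryote-specific
    paste0("eL", c(6, 8, 13:15, 18:22, 24, 27:34, 36:43)),
    "P1", "P2", "P1.P2",
    # small subunit, universal
    paste0("uS", c(2:5, 7:15, 17, 19)),
    # small subunit, eukaryote-specific
    paste0("eS", c(1, 4, 6:8, 10, 12, 17, 19, 21, 24:28, 30, 31)),
    "RACK1"
  )
}

#' Check protein names in a structure against a nomenclature
#'
#' Reports chains whose annotated `protein_name` family is absent from the
#' accepted nomenclature. Paralog suffixes after the family name (e.g.
#' `uL30_RPL7C`) are stripped before lookup. The structure is not modified.
#'
#' @param structure A [load_structure()] result.
#' @param nomenclature Character vector of accepted family names,
#'   default [rp_nomenclature()].
#' @return A tibble of offending chains (`chain_id`, `protein_name`,
#'   `family`); zero rows when all names validate.
#' @export
validate_annotation <- function(structure, nomenclature = rp_nomenclature()) {
  stopifnot(inherits(structure, "complex_structure"))
  if (length(nomenclature) == 0) {
    stop_structenrich("nomenclature must be non-empty",
                      "structenrich_validation_error")
  }
  structure$chains %>%
    mutate(family = sub("_.*$", "", .data$protein_name),
           # zero-padded synthetic names (uL01) match their family (uL1)
           family = sub("^([ue][LS])0+(\\d)", "\\1\\2", .data$family)) %>%
    filter(!.data$family %in% nomenclature) %>%
    select(all_of(c("chain_id", "protein_name", "family")))
}
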