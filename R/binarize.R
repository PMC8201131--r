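#' Normalize abundances to their subunit total per sample
#'
#' Divides each protein's abundance by the summed abundance of all
#' proteins of its subunit (40S or 60S) within the same sample, so that
#' within one sample the normalized values of each subunit sum to one.
#' This removes the varying amount of 40S and 60S material across
#' sucrose-gradient fractions.
#'
#' @param abundance Long tibble with columns `protein`, `subunit`,
#'   `sample`, `abundance` (plus any metadata columns, which are kept).
#' @return The input with an `nx` column (normalized abundance).
#' @export
normalize_by_subunit <- function(abundance) {
  abundance <- as_tibble(abundance)
  needed <- c("protein", "subunit", "sample", "abundance")
  miss <- setdiff(needed, names(abundance))
  if (length(miss) > 0) {
    stop_structenrich(paste0("abundance table is missing column(s): ",
                             paste(miss, collapse = ", ")),
                      "structenrich_validation_error")
  }
  if (any(abundance$abundance < 0, na.rm = TRUE)) {
    stop_structenrich("abundances must be non-negative",
                      "structenrich_validation_error")
  }
  out <- abundance %>%
    group_by(.data$sample, .data$subunit) %>%
    mutate(.total = sum(.data$abundance, na.rm = TRUE)) %>%
    ungroup()
  bad <- out %>% filter(.data$.total == 0) %>% distinct(.data$sample)
  if (nrow(bad) > 0) {
    stop_structenrich(
      paste0("all-zero subunit abundance in sample(s): ",
             paste(bad$sample, collapse = ", ")),
      "structenrich_normalization_error"
    )
  }
  out %>%
    mutate(nx = .data$abundance / .data$.total) %>%
    select(-all_of(".total"))
}

#' Log ratios between the 60S and the polysome fraction
#'
#' Within each genotype-by-temperature group, computes for every protein
#' the natural log of the mean normalized 60S abundance over the mean
#' normalized polysome abundance, averaging across replicates. Only
#' proteins observed (non-missing, positive) in every replicate of both
#' fractions qualify (complete-presence filter).
#'
#' @param nx Output of [normalize_by_subunit()] with metadata columns
#'   `genotype`, `temperature`, `fraction` (values include `"60S"` and
#'   `"polysome"`) and `replicate`.
#' @param numerator,denominator Fraction labels to compare,
#'   default `"60S"` over `"polysome"`.
#' @return Tibble with `protein`, `genotype`, `temperature`, `ln_ratio`;
#'   empty (with a warning) when no protein qualifies.
#' @export
ln_ratio_60s_polysome <- function(nx, numerator = "60S",
                                  denominator = "polysome") {
  nx <- as_tibble(nx)
  needed <- c("protein", "genotype", "temperature", "fraction",
              "replicate", "nx")
  miss <- setdiff(needed, names(nx))
  if (length(miss) > 0) {
    stop_structenrich(paste0("missing column(s): ",
                             paste(miss, collapse = ", ")),
                      "structenrich_validation_error")
  }
  dat <- nx %>% filter(.data$fraction %in% c(numerator, denominator))
  n_reps <- dat %>%
    distinct(.data$genotype, .data$temperature, .data$fraction,
             .data$replicate) %>%
    group_by(.data$genotype, .data$temperature, .data$fraction) %>%
    summarise(n_rep = n(), .groups = "drop")
  kept <- dat %>%
    group_by(.data$protein, .data$genotype, .data$temperature,
             .data$fraction) %>%
    summarise(n_obs = sum(!is.na(.data$nx) & .data$nx > 0),
              mean_nx = mean(.data$nx[!is.na(.data$nx) & .data$nx > 0]),
              .groups = "drop") %>%
    left_join(n_reps, by = c("genotype", "temperature", "fraction")) %>%
    filter(.data$n_obs == .data$n_rep) %>%
    select(-all_of(c("n_obs", "n_rep"))) %>%
    tidyr::pivot_wider(names_from = "fraction", values_from = "mean_nx")
  empty <- tibble(protein = character(), genotype = character(),
                  temperature = character(), ln_ratio = double())
  if (nrow(kept) == 0 ||
      !all(c(numerator, denominator) %in% names(kept))) {
    rlang::warn("no protein passes the complete-presence filter")
    return(empty)
  }
  out <- kept %>%
    filter(!is.na(.data[[numerator]]), !is.na(.data[[denominator]])) %>%
    mutate(ln_ratio = log(.data[[numerator]] / .data[[denominator]])) %>%
    select(all_of(c("protein", "genotype", "temperature", "ln_ratio")))
  if (nrow(out) == 0) {
    rlang::warn("no protein passes the complete-presence filter")
  }
  out
}

#' Classify a 60S:polysome log ratio into display bins
#'
#' Bins: `high_increase` (1 < r < 2), `increase` (0 < r <= 1), `decrease`
#' (-1 <= r < 0), `no_change` (|r| below `tol`); ratios at or beyond the
#' displayed range (r >= 2 or r < -1) are flagged `out_of_range`.
#'
#' @param r Numeric vector of natural-log ratios.
#' @param tol Resolution below which a ratio counts as no change,
#'   default 1e-12.
#' @return Character vector with values `high_increase`, `increase`,
#'   `decrease`, `no_change`, `out_of_range`.
#' @export
classify_ratio <- function(r, tol = 1e-12) {
  if (any(!is.finite(r))) {
    stop_structenrich("ratios must be finite",
                      "structenrich_validation_error")
  }
  dplyr::case_when(
    abs(r) < tol ~ "no_change",
    r > 1 & r < 2 ~ "high_increase",
    r > 0 & r <= 1 ~ "increase",
    r >= -1 & r < 0 ~ "decrease",
    TRUE ~ "out_of_range"
  )
}

#' Classify a gene family's paralog response
#'
#' Three scenarios over the significant paralogs of one family: `inverse`
#' when at least two paralogs are significantly regulated in opposite
#' directions, otherwise `up_only` / `down_only` when at least one paralog
#' is significantly up / down, else `unchanged`. Invariant to paralog
#' order.
#'
#' @param directions Character vector of per-paralog significant
#'   directions, values in `"up"`, `"down"`, `"none"`.
#' @return One of `"inverse"`, `"up_only"`, `"down_only"`, `"unchanged"`.
#' @export
classify_family_response <- function(directions) {
  if (!all(directions %in% c("up", "down", "none"))) {
    stop_structenrich("directions must be 'up', 'down' or 'none'",
                      "structenrich_validation_error")
  }
  has_up <- any(directions == "up")
  has_down <- any(directions == "down")
  if (has_up && has_down) "inverse"
  else if (has_up) "up_only"
  else if (has_down) "down_only"
  else "unchanged"
}

#' Build the binary significance layers
#'
#' Transforms family-level responses into the six binary layers used for
#' spatial testing. Transcriptome layers from paralog-response scenarios:
#' `1T` marks inversely regulated families, `2T` adds up-regulated, `3T`
#' adds down-regulated families. Proteome layers from significance flags:
#' `1P` significant 60S:polysome ratio change, `2P` significant polysome
#' change, `3P` their union. Family names are mapped to structure node
#' names; families without a matching node are excluded and reported in
#' the `unmapped` attribute.
#'
#' @param responses Tibble with columns `family` and `scenario` (values
#'   from [classify_family_response()]); may be `NULL` when only proteome
#'   layers are requested.
#' @param ratio_significant Character vector of families with a
#'   significant 60S:polysome ratio change (layer 1P).
#' @param polysome_significant Character vector of families with a
#'   significant polysome abundance change (layer 2P).
#' @param nodes Character vector of structure node (protein family)
#'   names the calls are mapped onto.
#' @param layers Which layers to emit; default all six.
#' @return Long tibble `protein`, `layer_id`, `call` covering every node
#'   for every requested layer, with attribute `unmapped` listing
#'   families that matched no node.
#' @export
build_binary_layers <- function(responses = NULL,
                                ratio_significant = character(),
                                polysome_significant = character(),
                                nodes,
                                layers = c("1T", "2T", "3T",
                                           "1P", "2P", "3P")) {
  stopifnot(length(nodes) > 0)
  scen <- if (is.null(responses)) {
    tibble(family = character(), scenario = character())
  } else {
    as_tibble(responses)
  }
  fam_in <- function(scenarios) {
    unique(scen$family[scen$scenario %in% scenarios])
  }
  layer_families <- list(
    "1T" = fam_in("inverse"),
    "2T" = fam_in(c("inverse", "up_only")),
    "3T" = fam_in(c("inverse", "up_only", "down_only")),
    "1P" = unique(ratio_significant),
    "2P" = unique(polysome_significant),
    "3P" = unique(c(ratio_significant, polysome_significant))
  )
  requested <- names(layer_families) %in% layers
  all_named <- unique(unlist(layer_families[requested]))
  unmapped <- setdiff(all_named, nodes)
  out <- purrr::map_dfr(layers, function(l) {
    fams <- intersect(layer_families[[l]], nodes)
    tibble(protein = nodes, layer_id = l,
           call = as.integer(nodes %in% fams))
  })
  attr(out, "unmapped") <- unmapped
  out
}

#' Read / write binary layer tables
#'
#' Binary input TSVs carry columns `protein_name`, `layer_id`, `call`,
#' the machine-readable twin of per-layer significance tables.
#'
#' @param path TSV path.
#' @return For the reader: tibble `protein`, `layer_id`, `call`.
#' @export
read_binary_layers <- function(path) {
  df <- read_tsv_skip_comments(path)
  if ("protein_name" %in% names(df)) df <- rename(df,
                                                  protein = "protein_name")
  stopifnot(all(c("protein", "layer_id", "call") %in% names(df)))
  mutate(df, call = as.integer(.data$call))
}

#' @rdname read_binary_layers
#' @param layers Long tibble `protein`, `layer_id`, `call`.
#' @param header Extra header lines.
#' @export
write_binary_layers <- function(layers, path, header = character()) {
  df <- as_tibble(layers) %>%
    rename(protein_name = "protein") %>%
    select(all_of(c("protein_name", "layer_id", "call")))
  write_tsv_with_header(df, path, header)
}

#' Read an abundance matrix with a sample sheet
#'
#' The abundance TSV is proteins x samples (first columns `protein`,
#' `subunit`); the sample sheet maps sample names to `genotype`,
#' `temperature`, `fraction`, `replicate`.
#'
#' @param abundance_path Path to the wide abundance TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @return A long tibble ready for [normalize_by_subunit()].
#' @export
read_abundance_matrix <- function(abundance_path, samples_path) {
  wide <- read_tsv_skip_comments(abundance_path)
  samples <- read_tsv_skip_comments(samples_path)
  stopifnot(all(c("protein", "subunit") %in% names(wide)),
            all(c("sample", "genotype", "temperature", "fraction",
                  "replicate") %in% names(samples)))
  long <- wide %>%
    tidyr::pivot_longer(-all_of(intersect(names(wide),
                                          c("protein", "subunit",
                                            "family", "paralog"))),
                        names_to = "sample", values_to = "abundance")
  missing_samples <- setdiff(long$sample, samples$sample)
  if (length(missing_samples) > 0) {
    stop_structenrich(paste0("sample sheet is missing: ",
                             paste(missing_samples, collapse = ", ")),
                      "structenrich_validation_error")
  }
  left_join(long, samples, by = "sample")
}
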