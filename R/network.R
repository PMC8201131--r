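#' Build the protein-protein proximity network
#'
#' Two proteins are connected when at least one pair of residue centroids
#' (one residue from each protein) lies within the distance threshold
#' (default 8 Angstrom, boundary inclusive). Chains annotated with the same
#' protein name are merged into one node before edge construction. Contact
#' search uses a spatial cell grid with cell size equal to the threshold,
#' so only neighboring cells are compared.
#'
#' Edge weights: `contact_proportion` (default) divides each pair's contact
#' count by the total number of contacting residue pairs in the network,
#' reading "proportion of inter-residue contacts" with a global
#' denominator; `contact_count` keeps raw counts. Transit probabilities are
#' identical under both modes because the global constant cancels.
#'
#' @param structure A `complex_structure` with centroids computed.
#' @param distance_threshold Contact threshold in Angstrom (> 0), default 8.
#' @param weight_mode `"contact_proportion"` or `"contact_count"`.
#' @return An object of class `proximity_network`: list with tibbles
#'   `nodes` (`node`, `subunit`, `n_residues`), `edges` (`from`, `to`,
#'   `n_contacts`, `weight`; `from < to`), `contacts` (per contacting
#'   residue pair), and `config`.
#' @export
build_contact_network <- function(structure, distance_threshold = 8,
                                  weight_mode = c("contact_proportion",
                                                  "contact_count")) {
  stopifnot(inherits(structure, "complex_structure"))
  weight_mode <- match.arg(weight_mode)
  assert_scalar_number(distance_threshold, "distance_threshold", lower = 0)
  if (distance_threshold <= 0) {
    stop_structenrich("distance_threshold must be > 0",
                      "structenrich_validation_error")
  }
  if (is.null(structure$residues)) {
    stop_structenrich(
      "structure has no residue centroids; run compute_centroids() first",
      "structenrich_state_error"
    )
  }
  res <- structure$residues
  nodes <- res %>%
    group_by(node = .data$protein_name) %>%
    summarise(subunit = first(.data$subunit),
              n_residues = n(), .groups = "drop") %>%
    arrange(.data$node)
  if (nrow(nodes) < 2) {
    stop_structenrich("need at least 2 distinct proteins to build a network",
                      "structenrich_degenerate_error")
  }

  contacts <- grid_contacts(res, distance_threshold)

  edges <- contacts %>%
    group_by(from = .data$node_a, to = .data$node_b) %>%
    summarise(n_contacts = n(), .groups = "drop") %>%
    arrange(.data$from, .data$to)
  edges$weight <- if (weight_mode == "contact_proportion" &&
                      nrow(edges) > 0) {
    edges$n_contacts / sum(edges$n_contacts)
  } else {
    as.double(edges$n_contacts)
  }

  structure(
    list(
      nodes = nodes,
      edges = edges,
      contacts = contacts,
      config = list(distance_threshold = distance_threshold,
                    weight_mode = weight_mode),
      structure_id = structure$structure_id
    ),
    class = "proximity_network"
  )
}

# Cell-grid contact detection between residue centroids of distinct
# proteins. Returns one row per contacting residue pair (node_a < node_b).
grid_contacts <- function(res, d_t) {
  pts <- res %>%
    mutate(idx = row_number(),
           cx = as.integer(floor(.data$x / d_t)),
           cy = as.integer(floor(.data$y / d_t)),
           cz = as.integer(floor(.data$z / d_t)))
  offsets <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  cand <- purrr::map_dfr(seq_len(nrow(offsets)), function(k) {
    shifted <- pts %>%
      mutate(cx = .data$cx + offsets$ox[k],
             cy = .data$cy + offsets$oy[k],
             cz = .data$cz + offsets$oz[k])
    inner_join(
      select(pts, all_of(c("idx", "protein_name", "chain_id", "residue_id",
                           "x", "y", "z", "cx", "cy", "cz"))),
      select(shifted, all_of(c("idx", "protein_name", "chain_id",
                               "residue_id", "x", "y", "z",
                               "cx", "cy", "cz"))),
      by = c("cx", "cy", "cz"), suffix = c("_a", "_b"),
      relationship = "many-to-many"
    ) %>%
      filter(.data$idx_a < .data$idx_b,
             .data$protein_name_a != .data$protein_name_b)
  })
  cand <- distinct(cand, .data$idx_a, .data$idx_b, .keep_all = TRUE)
  cand <- cand %>%
    mutate(distance = sqrt((.data$x_a - .data$x_b)^2 +
                           (.data$y_a - .data$y_b)^2 +
                           (.data$z_a - .data$z_b)^2)) %>%
    filter(.data$distance <= d_t)
  # orient each pair so node_a < node_b
  flip <- cand$protein_name_a > cand$protein_name_b
  pick <- function(yes, no) as.character(ifelse(flip, yes, no))
  tibble(
    node_a = pick(cand$protein_name_b, cand$protein_name_a),
    node_b = pick(cand$protein_name_a, cand$protein_name_b),
    chain_a = pick(cand$chain_id_b, cand$chain_id_a),
    chain_b = pick(cand$chain_id_a, cand$chain_id_b),
    residue_a = pick(cand$residue_id_b, cand$residue_id_a),
    residue_b = pick(cand$residue_id_a, cand$residue_id_b),
    distance = as.double(cand$distance)
  ) %>%
    arrange(.data$node_a, .data$node_b, .data$residue_a, .data$residue_b)
}

#' Construct a proximity network from explicit node and edge tables
#'
#' Mainly used by fixture generators and file import; performs the same
#' validity checks as [build_contact_network()] output.
#'
#' @param nodes Tibble with at least a `node` column.
#' @param edges Tibble with `from`, `to`, `n_contacts` and optionally
#'   `weight` (recomputed from `weight_mode` when absent).
#' @param weight_mode Weighting scheme, as in [build_contact_network()].
#' @param distance_threshold Threshold recorded in the config.
#' @param structure_id Identifier recorded on the network.
#' @return A `proximity_network`.
#' @export
new_proximity_network <- function(nodes, edges,
                                  weight_mode = "contact_proportion",
                                  distance_threshold = 8,
                                  structure_id = "synthetic") {
  nodes <- as_tibble(nodes)
  if (!"subunit" %in% names(nodes)) nodes$subunit <- NA_character_
  if (!"n_residues" %in% names(nodes)) nodes$n_residues <- NA_integer_
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"n_contacts" %in% names(edges)) edges$n_contacts <- 1L
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  if (any(edges$from == edges$to)) {
    stop_structenrich("self-edges are not allowed",
                      "structenrich_validation_error")
  }
  edges <- edges %>% arrange(.data$from, .data$to)
  if (anyDuplicated(edge_key(edges$from, edges$to))) {
    stop_structenrich("duplicated edges", "structenrich_validation_error")
  }
  bad <- setdiff(c(edges$from, edges$to), nodes$node)
  if (length(bad) > 0) {
    stop_structenrich(paste0("edge endpoints not in node table: ",
                             paste(unique(bad), collapse = ", ")),
                      "structenrich_validation_error")
  }
  if (!"weight" %in% names(edges)) {
    edges$weight <- if (weight_mode == "contact_proportion" &&
                        nrow(edges) > 0) {
      edges$n_contacts / sum(edges$n_contacts)
    } else {
      as.double(edges$n_contacts)
    }
  }
  structure(
    list(nodes = arrange(nodes, .data$node), edges = edges,
         contacts = NULL,
         config = list(distance_threshold = distance_threshold,
                       weight_mode = weight_mode),
         structure_id = structure_id),
    class = "proximity_network"
  )
}

#' @export
print.proximity_network <- function(x, ...) {
  cat("<proximity_network>", x$structure_id, "\n")
  cat("  nodes:", nrow(x$nodes), "| edges:", nrow(x$edges),
      "| d_t:", x$config$distance_threshold, "A",
      "| weights:", x$config$weight_mode, "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.proximity_network <- function(x, ...) x$edges

#' Derive the random-walk transit model
#'
#' For every ordered neighbor pair the transit probability is the edge
#' weight divided by the node strength (sum of the node's edge weights),
#' so each non-isolated node's outgoing probabilities sum to one. Isolated
#' nodes are flagged absorbing: a walk reaching one stops there.
#'
#' @param network A `proximity_network` with at least one edge.
#' @return An object of class `transit_model` with tibbles `transitions`
#'   (`from`, `to`, `weight`, `prob`) and `nodes` (`node`, `strength`,
#'   `absorbing`).
#' @export
transit_probabilities <- function(network) {
  stopifnot(inherits(network, "proximity_network"))
  if (nrow(network$edges) == 0) {
    stop_structenrich("network has no edges", "structenrich_degenerate_error")
  }
  if (all(network$edges$weight == 0)) {
    stop_structenrich("all edge weights are zero",
                      "structenrich_numeric_error")
  }
  if (any(network$edges$weight <= 0)) {
    stop_structenrich("edge weights must be positive",
                      "structenrich_validation_error")
  }
  e <- network$edges
  directed <- bind_rows(
    tibble(from = e$from, to = e$to, weight = e$weight),
    tibble(from = e$to, to = e$from, weight = e$weight)
  )
  strength <- directed %>%
    group_by(node = .data$from) %>%
    summarise(strength = sum(.data$weight), .groups = "drop")
  nodes <- network$nodes %>%
    select(all_of("node")) %>%
    left_join(strength, by = "node") %>%
    mutate(strength = ifelse(is.na(.data$strength), 0, .data$strength),
           absorbing = .data$strength == 0)
  transitions <- directed %>%
    left_join(strength, by = c("from" = "node")) %>%
    mutate(prob = .data$weight / .data$strength) %>%
    select(all_of(c("from", "to", "weight", "prob"))) %>%
    arrange(.data$from, .data$to)
  adj <- split(transitions[c("to", "prob")], transitions$from)
  structure(
    list(transitions = transitions, nodes = nodes, adjacency = adj,
         structure_id = network$structure_id),
    class = "transit_model"
  )
}

#' @export
print.transit_model <- function(x, ...) {
  cat("<transit_model>", x$structure_id, "\n")
  cat("  nodes:", nrow(x$nodes),
      "| absorbing:", sum(x$nodes$absorbing), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.transit_model <- function(x, ...) x$transitions

#' Convert a proximity network to an igraph graph
#'
#' @param network A `proximity_network`.
#' @return An undirected weighted `igraph` graph with `n_contacts` and
#'   `subunit` attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "proximity_network"))
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes %>%
      mutate(subunit = ifelse(is.na(.data$subunit), "", .data$subunit))
  )
  g
}

#' Export a proximity network to a file
#'
#' `edge_list_tsv` writes a self-contained TSV: `#node` header lines carry
#' the node table (so 0-edge networks and isolated nodes round-trip), and
#' weights are serialized with 17 significant digits so that re-import
#' reproduces them exactly. `graphml` goes through igraph.
#'
#' @param network A `proximity_network`.
#' @param path Output path.
#' @param format `"edge_list_tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edge_list_tsv", "graphml")) {
  stopifnot(inherits(network, "proximity_network"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    stop_structenrich(paste0("directory does not exist: ", dirname(path)),
                      "structenrich_io_error")
  }
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
    return(invisible(path))
  }
  header <- c(
    paste0("structure_id=", network$structure_id),
    paste0("distance_threshold=", network$config$distance_threshold),
    paste0("weight_mode=", network$config$weight_mode),
    paste0("node\t", network$nodes$node, "\t",
           ifelse(is.na(network$nodes$subunit), "",
                  network$nodes$subunit))
  )
  df <- tibble(
    source = network$edges$from,
    target = network$edges$to,
    weight = format_full(network$edges$weight),
    n_contacts = network$edges$n_contacts
  )
  write_tsv_with_header(df, path, header)
}

#' Import a proximity network written by [export_network()]
#'
#' @param path Path to an edge-list TSV or GraphML file.
#' @param format File format; guessed from the extension when omitted.
#' @return A `proximity_network` (without per-residue contact lists).
#' @export
import_network <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop_structenrich(paste0("file not found: ", path),
                      "structenrich_io_error")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path)) "graphml" else "edge_list_tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    edf <- igraph::as_data_frame(g, what = "edges")
    vdf <- igraph::as_data_frame(g, what = "vertices")
    nodes <- tibble(node = vdf$name,
                    subunit = vdf$subunit %||% NA_character_,
                    n_residues = vdf$n_residues %||% NA_integer_)
    edges <- tibble(from = edf$from, to = edf$to,
                    n_contacts = edf$n_contacts %||% NA_integer_,
                    weight = edf$weight)
    return(new_proximity_network(nodes, edges))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get_val <- function(key) {
    m <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(m) == 0) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  node_lines <- hdr[startsWith(hdr, "# node\t")]
  node_parts <- stringr::str_split(sub("^# node\t", "", node_lines), "\t")
  nodes <- tibble(
    node = purrr::map_chr(node_parts, 1),
    subunit = purrr::map_chr(node_parts,
                             ~ if (length(.x) > 1 && nzchar(.x[2]))
                                 .x[2] else NA_character_)
  )
  body <- lines[!startsWith(lines, "#")]
  edges <- if (length(body) > 1) {
    # base parser: strtod round-trips %.17g-serialized doubles exactly
    utils::read.delim(text = paste(body, collapse = "\n"),
                      stringsAsFactors = FALSE) %>%
      as_tibble() %>%
      rename(from = "source", to = "target")
  } else {
    tibble(from = character(), to = character(),
           weight = double(), n_contacts = integer())
  }
  net <- new_proximity_network(
    nodes, edges,
    weight_mode = get_val("weight_mode") %||% "contact_proportion",
    distance_threshold = as.numeric(get_val("distance_threshold") %||% 8),
    structure_id = get_val("structure_id") %||% "imported"
  )
  net
}
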