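#' Sampler configuration
#'
#' Bundles the parameters of the random-walk region sampler: walk length
#' (steps per walk), iteration number (independent walks per start node),
#' the consensus membership fraction, and the RNG seed.
#'
#' @param walk_length Steps per walk (`WL >= 0`), default 10.
#' @param iterations Independent walks per start node (`IN >= 1`),
#'   default 20.
#' @param consensus_fraction A node enters the consensus region of a start
#'   node when it is visited in at least this fraction of the iterations;
#'   in (0, 1], default 0.5.
#' @param seed Integer seed; makes region sampling fully reproducible.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(walk_length = 10, iterations = 20,
                           consensus_fraction = 0.5, seed = 1L) {
  assert_scalar_number(walk_length, "walk_length", lower = 0)
  assert_scalar_number(iterations, "iterations", lower = 1)
  assert_scalar_number(consensus_fraction, "consensus_fraction", lower = 0)
  if (consensus_fraction <= 0 || consensus_fraction > 1) {
    stop_structenrich("consensus_fraction must be in (0, 1]",
                      "structenrich_validation_error")
  }
  structure(
    list(walk_length = as.integer(walk_length),
         iterations = as.integer(iterations),
         consensus_fraction = consensus_fraction,
         seed = as.integer(seed)),
    class = "sampler_config"
  )
}

#' Compose a run identifier
#'
#' Format: `<structure_id>_d_t_<threshold>_IN<iterations>_WL<walk_length>`,
#' e.g. `4v7e_d_t_8_IN20_WL10`, so every output names the exact
#' configuration that produced it.
#'
#' @param structure_id Structure identifier.
#' @param distance_threshold Contact threshold in Angstrom.
#' @param iterations,walk_length Sampler parameters.
#' @return A string.
#' @export
make_run_id <- function(structure_id, distance_threshold, iterations,
                        walk_length) {
  sprintf("%s_d_t_%g_IN%d_WL%d", structure_id, distance_threshold,
          as.integer(iterations), as.integer(walk_length))
}

# Fast internal walk: character vector of visited nodes (start first).
walk_path <- function(adjacency, absorbing, start, walk_length) {
  path <- character(walk_length + 1)
  path[1] <- start
  cur <- start
  for (i in seq_len(walk_length)) {
    nb <- adjacency[[cur]]
    if (is.null(nb) || nrow(nb) == 0) return(path[seq_len(i)])
    cur <- if (nrow(nb) == 1) nb$to else
      sample(nb$to, 1, prob = nb$prob)
    path[i + 1] <- cur
  }
  path
}

#' Run one weighted random walk
#'
#' Starting from `start`, takes up to `walk_length` steps, drawing each
#' next node from the start node's current transit distribution (edge
#' weight over node strength). Revisits are allowed; a walk reaching an
#' absorbing (isolated) node is truncated. Uses the current R RNG stream;
#' seed with `set.seed()` or `withr::with_seed()` for reproducibility.
#'
#' @param model A `transit_model`.
#' @param start Start node name.
#' @param walk_length Number of steps (`>= 0`).
#' @return A tibble with columns `step` (0-based) and `node`.
#' @export
random_walk <- function(model, start, walk_length = 10) {
  stopifnot(inherits(model, "transit_model"))
  assert_scalar_number(walk_length, "walk_length", lower = 0)
  if (!start %in% model$nodes$node) {
    stop_structenrich(paste0("unknown start node: ", start),
                      "structenrich_key_error")
  }
  p <- walk_path(model$adjacency, NULL, start, as.integer(walk_length))
  tibble(step = seq_along(p) - 1L, node = p)
}

#' Consensus region for one start node
#'
#' Runs `iterations` independent walks from `start`; the region consists
#' of the start node plus every node visited in at least
#' `consensus_fraction * iterations` of the walks (a node counts once per
#' walk, however often the walk revisits it).
#'
#' @param model A `transit_model`.
#' @param start Start node name.
#' @param config A [sampler_config()]. When its `seed` is non-`NULL` the
#'   walks run under that seed (restoring the caller's RNG state);
#'   otherwise the current RNG stream is used.
#' @return A one-row tibble: `start`, `members` (list-column, sorted),
#'   `n_members`.
#' @export
consensus_region <- function(model, start, config = sampler_config()) {
  stopifnot(inherits(model, "transit_model"),
            inherits(config, "sampler_config"))
  if (!start %in% model$nodes$node) {
    stop_structenrich(paste0("unknown start node: ", start),
                      "structenrich_key_error")
  }
  run <- function() consensus_members(model$adjacency, start, config)
  members <- if (is.null(config$seed)) run() else
    withr::with_seed(config$seed, run())
  tibble(start = start, members = list(members),
         n_members = length(members))
}

consensus_members <- function(adjacency, start, config) {
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(config$iterations)) {
    visited <- unique(walk_path(adjacency, NULL, start, config$walk_length))
    for (v in visited) {
      counts[[v]] <- (counts[[v]] %||% 0L) + 1L
    }
  }
  nodes <- ls(counts)
  hits <- vapply(nodes, function(v) counts[[v]], integer(1))
  thr <- config$consensus_fraction * config$iterations - 1e-9
  sort(union(start, nodes[hits >= thr]))
}

# Edge keys of the subgraph induced by a member set.
induced_edge_keys <- function(network, members) {
  e <- network$edges
  keep <- e$from %in% members & e$to %in% members
  edge_key(e$from[keep], e$to[keep])
}

#' Greedy minimum edge set cover over pre-regions
#'
#' Selects pre-regions until their induced edges cover the whole edge
#' universe of the network, greedily taking the region that covers the
#' most still-uncovered edges; ties broken by larger member count, then
#' lexicographic start node. Errors when the pre-regions cannot cover
#' every edge.
#'
#' @param network A `proximity_network`.
#' @param pre_regions Tibble with columns `start` and list-column
#'   `members` (e.g. rows from [consensus_region()]).
#' @param run_id Run identifier stamped on the result (optional).
#' @param seed Seed recorded on the result (optional bookkeeping).
#' @return An object of class `region_set`; its `regions` tibble has
#'   `region_id`, `start`, `members`, `n_members`, `n_edges_covered`
#'   (newly covered at selection time), `n_edges_induced`.
#' @export
min_set_cover <- function(network, pre_regions, run_id = NULL, seed = NULL) {
  stopifnot(inherits(network, "proximity_network"))
  pre_regions <- as_tibble(pre_regions)
  universe <- edge_key(network$edges$from, network$edges$to)
  region_edges <- purrr::map(pre_regions$members,
                             ~ induced_edge_keys(network, .x))
  covered_union <- unique(unlist(region_edges))
  missing <- setdiff(universe, covered_union)
  if (length(missing) > 0) {
    stop_structenrich(
      paste0("pre-regions do not cover the edge universe; uncovered: ",
             paste(missing, collapse = ", ")),
      "structenrich_coverage_error",
      uncovered = missing
    )
  }
  uncovered <- universe
  selected <- integer()
  gains <- integer(nrow(pre_regions))
  n_members <- lengths(pre_regions$members)
  while (length(uncovered) > 0) {
    gain <- vapply(region_edges, function(k) sum(k %in% uncovered),
                   integer(1))
    gain[selected] <- -1L
    best <- which(gain == max(gain))
    if (length(best) > 1) {
      best <- best[order(-n_members[best], pre_regions$start[best])][1]
    }
    selected <- c(selected, best)
    gains[best] <- gain[best]
    uncovered <- setdiff(uncovered, region_edges[[best]])
  }
  regions <- pre_regions[selected, ] %>%
    mutate(
      n_members = lengths(.data$members),
      n_edges_covered = gains[selected],
      n_edges_induced = lengths(region_edges[selected]),
      region_id = paste0(.data$start,
                         ifelse(is.null(run_id), "", paste0("_", run_id)))
    ) %>%
    select(all_of(c("region_id", "start", "members", "n_members",
                    "n_edges_covered", "n_edges_induced")))
  overlap <- sum(regions$n_edges_induced) - length(universe)
  structure(
    list(run_id = run_id, seed = seed, regions = regions,
         n_edges_total = length(universe), edge_overlap = overlap,
         structure_id = network$structure_id),
    class = "region_set"
  )
}

#' Sample structural regions from a proximity network
#'
#' The full region-definition step: a consensus region is grown from every
#' node of the network, the pool is reduced by a greedy minimum edge set
#' cover, and the result is stamped with a run identifier encoding the
#' configuration. Fully reproducible from (network, config): all walks run
#' under `config$seed`.
#'
#' Because finite walks can leave some edge of the universe outside every
#' consensus region, the pre-region pool is augmented with a two-node
#' fallback region per uncovered edge before the cover step
#' (`ensure_coverage = TRUE`, the default), so the cover's precondition
#' always holds; fallback regions are marked in the output.
#'
#' @param model A `transit_model` derived from `network`.
#' @param network The `proximity_network`.
#' @param config A [sampler_config()].
#' @param ensure_coverage Add per-edge fallback pre-regions when consensus
#'   regions leave edges uncovered.
#' @return A `region_set`; regions whose member set does not induce a
#'   connected subgraph are flagged in the `connected` column (logged,
#'   not fatal).
#' @export
sample_regions <- function(model, network, config = sampler_config(),
                           ensure_coverage = TRUE) {
  stopifnot(inherits(model, "transit_model"),
            inherits(network, "proximity_network"),
            inherits(config, "sampler_config"))
  starts <- sort(network$nodes$node)
  inner_cfg <- config
  inner_cfg$seed <- NULL
  pre <- withr::with_seed(config$seed, {
    purrr::map_dfr(starts, function(s)
      consensus_region(model, s, inner_cfg))
  })
  pre$fallback <- FALSE
  if (ensure_coverage) {
    universe <- edge_key(network$edges$from, network$edges$to)
    covered <- unique(unlist(purrr::map(pre$members,
                                        ~ induced_edge_keys(network, .x))))
    miss <- setdiff(universe, covered)
    if (length(miss) > 0) {
      ends <- stringr::str_split(miss, stringr::fixed("|"))
      extra <- tibble(
        start = purrr::map_chr(ends, 1),
        members = purrr::map(ends, sort),
        n_members = 2L,
        fallback = TRUE
      )
      pre <- bind_rows(pre, extra)
    }
  }
  run_id <- make_run_id(network$structure_id,
                        network$config$distance_threshold,
                        config$iterations, config$walk_length)
  rs <- min_set_cover(network, pre, run_id = run_id, seed = config$seed)
  rs$config <- config
  # fallback regions need distinct ids (same start can head both kinds)
  fb <- pre$fallback[match_regions(pre, rs$regions)]
  rs$regions$fallback <- fb
  rs$regions$region_id <- ifelse(
    fb,
    paste0(purrr::map_chr(rs$regions$members, paste, collapse = "."),
           "_", run_id),
    rs$regions$region_id
  )
  rs$regions$connected <- purrr::map_lgl(rs$regions$members,
                                         ~ is_connected_subset(network, .x))
  n_disc <- sum(!rs$regions$connected)
  if (n_disc > 0) {
    rlang::inform(paste0(n_disc, " region(s) induce a disconnected ",
                         "subgraph (flagged in `connected`)"))
  }
  rs
}

# Match selected regions back to pre-region rows (by start + member set).
match_regions <- function(pre, regions) {
  pre_id <- paste(pre$start,
                  purrr::map_chr(pre$members, paste, collapse = "."))
  reg_id <- paste(regions$start,
                  purrr::map_chr(regions$members, paste, collapse = "."))
  match(reg_id, pre_id)
}

is_connected_subset <- function(network, members) {
  if (length(members) <= 1) return(TRUE)
  e <- network$edges
  keep <- e$from %in% members & e$to %in% members
  g <- igraph::graph_from_data_frame(e[keep, c("from", "to")],
                                     directed = FALSE,
                                     vertices = members)
  igraph::is_connected(g)
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", x$run_id %||% "", "\n")
  cat("  regions:", nrow(x$regions),
      "| edges covered:", x$n_edges_total,
      "| overlap:", x$edge_overlap,
      "| seed:", x$seed %||% NA, "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.region_set <- function(x, ...) x$regions

#' Write a region table TSV
#'
#' Columns `region_id`, `run_id`, `start`, `members` (comma-separated
#' protein names) and `n_edges_covered`.
#'
#' @param region_set A `region_set`.
#' @param path Output path.
#' @param header Extra header lines.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(region_set, path, header = character()) {
  stopifnot(inherits(region_set, "region_set"))
  df <- region_set$regions %>%
    mutate(run_id = region_set$run_id %||% "",
           members = purrr::map_chr(.data$members, paste,
                                    collapse = ",")) %>%
    select(all_of(c("region_id", "run_id", "start", "members",
                    "n_edges_covered")))
  write_tsv_with_header(
    df, path,
    c(paste0("run_id=", region_set$run_id %||% ""),
      paste0("seed=", region_set$seed %||% ""), header)
  )
}

#' Read a region table written by [write_region_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with `region_id`, `run_id`, `start`, list-column
#'   `members`, `n_edges_covered`.
#' @export
read_region_table <- function(path) {
  df <- read_tsv_skip_comments(path)
  df %>%
    mutate(members = stringr::str_split(.data$members, ","),
           region_id = as.character(.data$region_id))
}
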