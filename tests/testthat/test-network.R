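# Proximity network construction, transit model, serialization.

test_that("chains beyond the threshold yield nodes without edges", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "GLY", "A", 2, 3, 0, 0),
    pdb_atom_line(3, "CA", " ", "ALA", "B", 1, 150, 0, 0),
    pdb_atom_line(4, "CA", " ", "ALA", "B", 2, 153, 0, 0)
  )
  path <- write_raw_pdb(withr::local_tempfile(fileext = ".pdb"), lines)
  st <- compute_centroids(load_structure(path,
                                         simple_annotation(c("A", "B"))))
  net <- build_contact_network(st)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 0)
})

test_that("a fully contacting pair counts all nine residue pairs", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "GLY", "A", 2, 1, 0, 0),
    pdb_atom_line(3, "CA", " ", "GLY", "A", 3, 2, 0, 0),
    pdb_atom_line(4, "CA", " ", "ALA", "B", 1, 5, 0, 0),
    pdb_atom_line(5, "CA", " ", "ALA", "B", 2, 6, 0, 0),
    pdb_atom_line(6, "CA", " ", "ALA", "B", 3, 7, 0, 0)
  )
  path <- write_raw_pdb(withr::local_tempfile(fileext = ".pdb"), lines)
  st <- compute_centroids(load_structure(path,
                                         simple_annotation(c("A", "B"))))
  net <- build_contact_network(st, distance_threshold = 8,
                               weight_mode = "contact_count")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$n_contacts, 9)
  expect_equal(net$edges$weight, 9)
})

test_that("grid contact search equals the brute-force all-pairs scan", {
  for (seed in 1:4) {
    fix <- generate_toy_complex(
      n_chains = 5 + seed, residues_per_chain = 8,
      layout = c("line", "ring", "lattice", "two_cliques")[seed],
      seed = seed)
    st <- compute_centroids(load_structure(fix$pdb_path, fix$annotation))
    net <- build_contact_network(st, weight_mode = "contact_count")
    oracle <- brute_contact_edges(st, 8)
    expect_equal(as.data.frame(net$edges[, c("from", "to",
                                             "n_contacts")]),
                 as.data.frame(oracle))
  }
})

test_that("contact boundary is inclusive and symmetric", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "ALA", "B", 1, 8, 0, 0)
  )
  path <- write_raw_pdb(withr::local_tempfile(fileext = ".pdb"), lines)
  st <- compute_centroids(load_structure(path,
                                         simple_annotation(c("A", "B"))))
  net <- build_contact_network(st, distance_threshold = 8)
  expect_equal(nrow(net$edges), 1)  # distance exactly 8 counts
  # contacts store node_a < node_b only once: symmetric by construction
  expect_true(all(net$edges$from < net$edges$to))
})

test_that("raising the threshold never removes edges or contacts", {
  fix <- generate_toy_complex(n_chains = 9, residues_per_chain = 6,
                              layout = "lattice", seed = 21)
  st <- compute_centroids(load_structure(fix$pdb_path, fix$annotation))
  prev_edges <- NULL
  prev_counts <- NULL
  for (d in c(4, 6, 8, 10, 12)) {
    net <- build_contact_network(st, distance_threshold = d,
                                 weight_mode = "contact_count")
    keys <- paste(net$edges$from, net$edges$to)
    if (!is.null(prev_edges)) {
      expect_true(all(prev_edges %in% keys))
      common <- intersect(prev_edges, keys)
      expect_true(all(net$edges$n_contacts[match(common, keys)] >=
                        prev_counts[match(common, prev_edges)]))
    }
    prev_edges <- keys
    prev_counts <- net$edges$n_contacts
  }
})

test_that("same-name chains merge into a single node", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "GLY", "B", 1, 3, 0, 0),
    pdb_atom_line(3, "CA", " ", "ALA", "C", 1, 30, 0, 0),
    pdb_atom_line(4, "CA", " ", "ALA", "D", 1, 33, 0, 0)
  )
  path <- write_raw_pdb(withr::local_tempfile(fileext = ".pdb"), lines)
  ann <- simple_annotation(c("A", "B", "C", "D"),
                           names = c("uL01", "uL01", "uL02", "uL02"))
  st <- suppressWarnings(load_structure(path, ann))
  net <- build_contact_network(compute_centroids(st))
  expect_equal(nrow(net$nodes), 2)
  # intra-node residue pairs are not contacts (no self-edges)
  expect_equal(nrow(net$edges), 0)
})

test_that("network preconditions raise typed errors", {
  fix <- generate_toy_complex(n_chains = 4, seed = 5)
  st <- load_structure(fix$pdb_path, fix$annotation)
  expect_error(build_contact_network(st),
               class = "structenrich_state_error")
  lines <- pdb_atom_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0)
  p1 <- write_raw_pdb(withr::local_tempfile(fileext = ".pdb"), lines)
  one <- compute_centroids(load_structure(p1, simple_annotation("A")))
  expect_error(build_contact_network(one),
               class = "structenrich_degenerate_error")
})

test_that("transit probabilities follow the weight-over-strength rule", {
  net <- new_proximity_network(
    tibble::tibble(node = c("x", "y", "z")),
    tibble::tibble(from = c("x", "x"), to = c("y", "z"),
                   n_contacts = c(2L, 6L), weight = c(2, 6)))
  tm <- transit_probabilities(net)
  px <- dplyr::filter(tm$transitions, from == "x")
  expect_equal(px$prob[px$to == "y"], 0.25)
  expect_equal(px$prob[px$to == "z"], 0.75)
  # single-neighbor node: probability one
  py <- dplyr::filter(tm$transitions, from == "y")
  expect_equal(py$prob, 1)
})

test_that("transit rows sum to one and modes agree", {
  for (seed in 1:5) {
    net <- random_fixture_network(6 + seed, seed = seed)
    tm <- transit_probabilities(net)
    sums <- tapply(tm$transitions$prob, tm$transitions$from, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    # contact_count weighting yields identical transit probabilities
    net2 <- new_proximity_network(net$nodes,
                                  dplyr::select(net$edges, -weight),
                                  weight_mode = "contact_count")
    tm2 <- transit_probabilities(net2)
    expect_equal(tm$transitions$prob, tm2$transitions$prob,
                 tolerance = 1e-14)
  }
})

test_that("isolated nodes are flagged absorbing", {
  net <- new_proximity_network(
    tibble::tibble(node = c("a", "b", "iso")),
    tibble::tibble(from = "a", to = "b", n_contacts = 1L))
  tm <- transit_probabilities(net)
  expect_true(tm$nodes$absorbing[tm$nodes$node == "iso"])
  expect_false(any(tm$nodes$absorbing[tm$nodes$node %in% c("a", "b")]))
})

test_that("transit model rejects degenerate networks", {
  net0 <- new_proximity_network(
    tibble::tibble(node = c("a", "b")),
    tibble::tibble(from = character(), to = character(),
                   n_contacts = integer(), weight = double()))
  expect_error(transit_probabilities(net0),
               class = "structenrich_degenerate_error")
  netz <- new_proximity_network(
    tibble::tibble(node = c("a", "b")),
    tibble::tibble(from = "a", to = "b", n_contacts = 1L, weight = 0))
  expect_error(transit_probabilities(netz),
               class = "structenrich_numeric_error")
})

test_that("edge-list TSV round-trip is exact", {
  net <- random_fixture_network(8, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, path)
  back <- import_network(path)
  expect_identical(back$nodes$node, net$nodes$node)
  expect_identical(back$edges$from, net$edges$from)
  expect_identical(back$edges$to, net$edges$to)
  expect_identical(back$edges$weight, net$edges$weight)  # bit-exact
  expect_identical(as.integer(back$edges$n_contacts),
                   as.integer(net$edges$n_contacts))
})

test_that("a zero-edge network exports its node list only", {
  net0 <- new_proximity_network(
    tibble::tibble(node = c("a", "b")),
    tibble::tibble(from = character(), to = character(),
                   n_contacts = integer(), weight = double()))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net0, path)
  back <- import_network(path)
  expect_equal(back$nodes$node, c("a", "b"))
  expect_equal(nrow(back$edges), 0)
})

test_that("graphml round-trip preserves topology and near-exact weights", {
  net <- random_fixture_network(7, seed = 9)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, format = "graphml")
  back <- import_network(path)
  expect_setequal(back$nodes$node, net$nodes$node)
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_setequal(key(back), key(net))
  expect_equal(back$edges$weight[match(key(net), key(back))],
               net$edges$weight, tolerance = 1e-12)
  expect_error(export_network(net, file.path(tempdir(), "no_dir_x",
                                             "f.tsv")),
               class = "structenrich_io_error")
})
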