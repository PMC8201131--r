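# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (double loops, full enumeration)
# and independent of the package's implementation paths.

# Brute-force all-pairs residue contact scan; returns an edge tibble
# (from < to) with contact counts, computed without any spatial index.
brute_contact_edges <- function(structure, d_t) {
  res <- structure$residues
  n <- nrow(res)
  hits <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (res$protein_name[i] == res$protein_name[j]) next
      d <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2 +
                  (res$z[i] - res$z[j])^2)
      if (d <= d_t) {
        a <- min(res$protein_name[i], res$protein_name[j])
        b <- max(res$protein_name[i], res$protein_name[j])
        hits[[length(hits) + 1]] <- c(a, b)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          n_contacts = integer()))
  }
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  names(df) <- c("from", "to")
  dplyr::count(df, from, to, name = "n_contacts") |>
    dplyr::arrange(from, to) |>
    tibble::as_tibble()
}

# Exact one-sided (greater) Fisher p by enumeration over achievable
# tables with the observed margins, using binomial coefficients directly.
brute_fisher_greater <- function(a, b, c, d) {
  k <- a + b; K <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  lo <- max(0, k - (N - K)); hi <- min(k, K)
  sup <- lo:hi
  pts <- exp(lchoose(K, sup) + lchoose(N - K, k - sup) - lchoose(N, k))
  sum(pts[sup >= a])
}

# Exhaustive minimum set cover size over <= 2^n subsets of pre-regions.
exhaustive_cover_size <- function(universe, region_edge_sets) {
  n <- length(region_edge_sets)
  best <- Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) >= best) next
    if (all(universe %in% unlist(region_edge_sets[idx]))) {
      best <- length(idx)
    }
  }
  best
}

# Random connected-ish weighted network fixture for transit-model tests.
random_fixture_network <- function(n_nodes, edge_prob = 0.4, seed = 1L) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    pairs <- t(utils::combn(n_nodes, 2))
    # spanning path guarantees no isolated nodes unless asked for
    keep <- stats::runif(nrow(pairs)) < edge_prob |
      (pairs[, 2] - pairs[, 1] == 1)
    edges <- tibble::tibble(
      from = nodes[pairs[keep, 1]],
      to = nodes[pairs[keep, 2]],
      n_contacts = sample(1:50, sum(keep), replace = TRUE)
    )
    new_proximity_network(tibble::tibble(node = nodes), edges,
                          structure_id = "fixture")
  })
}

# Raw PDB text writer for hand-crafted parsing fixtures (altlocs,
# HETATMs, insertion codes) independent of the package's writer.
pdb_atom_line <- function(serial, name, altloc, resname, chain, resno,
                          x, y, z, occ = 1, record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, altloc, resname, chain, resno,
          x, y, z, occ, 0)
}

write_raw_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

simple_annotation <- function(chain_ids, names = NULL, subunit = "60S") {
  if (is.null(names)) names <- sprintf("uL%02d", seq_along(chain_ids))
  tibble::tibble(chain_id = chain_ids, protein_name = names,
                 subunit = subunit, paralog_ids = "")
}
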