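# Synthetic fixture generators: toy complexes with a known contact graph,
# planted-module networks, binary calls with a planted enrichment, and
# abundance matrices with planted log ratios. All seed-deterministic, all
# carrying machine-readable ground truth for tests.

#' Generate a toy multi-chain complex with a known contact graph
#'
#' Places compact pseudo-chains in space so that the intended adjacency is
#' exactly realized at the default 8 Angstrom contact threshold, writes a
#' valid PDB file plus a chain-annotation TSV, and verifies the geometry
#' against a direct all-pairs distance scan at generation time (erroring
#' when the layout cannot guarantee its graph).
#'
#' Layouts: `two_cliques` (two fully connected groups separated by
#' `inter_group_gap`), `ring` (cycle over all chains; needs >= 6 chains
#' so that second-neighbor distances clear the threshold), `line` (path
#' graph), `lattice` (square grid, 4-neighborhood).
#'
#' Residues are single-atom by default so that the centroid equals the
#' coordinate; `atoms_per_residue > 1` spreads atoms around each residue
#' point and recenters them so the centroid is exact.
#'
#' @param n_chains Number of chains (<= 62, PDB single-character ids).
#' @param residues_per_chain Residues per chain.
#' @param layout One of `"two_cliques"`, `"ring"`, `"line"`, `"lattice"`.
#' @param distance_threshold Threshold the layout is designed for,
#'   default 8.
#' @param inter_group_gap Gap between the two cliques, default 50.
#' @param atoms_per_residue Atoms per residue, default 1.
#' @param seed RNG seed for the coordinate jitter.
#' @param dir Output directory (created); default a fresh tempdir.
#' @param subunits Optional per-chain subunit labels (recycled); default
#'   alternates `40S`/`60S`.
#' @return A list: `pdb_path`, `annotation_path`, `annotation` tibble,
#'   `expected_edges` tibble (`from`, `to` protein names), `chain_names`.
#' @export
generate_toy_complex <- function(n_chains = 8, residues_per_chain = 5,
                                 layout = c("two_cliques", "ring", "line",
                                            "lattice"),
                                 distance_threshold = 8,
                                 inter_group_gap = 50,
                                 atoms_per_residue = 1,
                                 seed = 1L, dir = NULL,
                                 subunits = NULL) {
  layout <- match.arg(layout)
  if (n_chains < 2 || n_chains > 62) {
    stop_structenrich("n_chains must be in 2..62",
                      "structenrich_generation_error")
  }
  if (layout == "ring" && n_chains < 6) {
    stop_structenrich(
      "ring layout needs >= 6 chains to keep non-neighbors apart",
      "structenrich_generation_error"
    )
  }
  jitter_r <- 0.4
  spacing <- distance_threshold - 2 * jitter_r - 0.5  # adjacent anchors
  anchors <- switch(
    layout,
    two_cliques = {
      k1 <- ceiling(n_chains / 2)
      k2 <- n_chains - k1
      clique_anchor <- function(k, offset) {
        # tight 3D grid, pairwise anchor distance <= 2*sqrt(3) ~ 3.5
        g <- expand.grid(x = 0:1, y = 0:1, z = 0:3)[seq_len(k), ] * 2
        as.matrix(g) + matrix(rep(c(offset, 0, 0), each = k), ncol = 3)
      }
      if (k1 > 16 || k2 > 16) {
        stop_structenrich("two_cliques supports at most 16 chains/group",
                          "structenrich_generation_error")
      }
      rbind(clique_anchor(k1, 0), clique_anchor(k2, inter_group_gap))
    },
    ring = {
      radius <- spacing / (2 * sin(pi / n_chains))
      th <- 2 * pi * (seq_len(n_chains) - 1) / n_chains
      cbind(radius * cos(th), radius * sin(th), 0)
    },
    line = cbind((seq_len(n_chains) - 1) * spacing, 0, 0),
    lattice = {
      ncol_g <- ceiling(sqrt(n_chains))
      ix <- (seq_len(n_chains) - 1) %% ncol_g
      iy <- (seq_len(n_chains) - 1) %/% ncol_g
      cbind(ix * spacing, iy * spacing, 0)
    }
  )
  intended <- switch(
    layout,
    two_cliques = {
      k1 <- ceiling(n_chains / 2)
      grp <- rep(1:2, c(k1, n_chains - k1))
      pairs <- t(utils::combn(n_chains, 2))
      pairs[grp[pairs[, 1]] == grp[pairs[, 2]], , drop = FALSE]
    },
    ring = cbind(seq_len(n_chains),
                 c(seq_len(n_chains)[-1], 1)),
    line = cbind(seq_len(n_chains - 1), 2:n_chains),
    lattice = {
      ncol_g <- ceiling(sqrt(n_chains))
      ix <- (seq_len(n_chains) - 1) %% ncol_g
      iy <- (seq_len(n_chains) - 1) %/% ncol_g
      pairs <- t(utils::combn(n_chains, 2))
      keep <- abs(ix[pairs[, 1]] - ix[pairs[, 2]]) +
        abs(iy[pairs[, 1]] - iy[pairs[, 2]]) == 1
      pairs[keep, , drop = FALSE]
    }
  )

  chain_ids <- c(LETTERS, letters, 0:9)[seq_len(n_chains)]
  families <- grep("^[ue][LS]", rp_nomenclature(), value = TRUE)
  chain_names <- families[seq_len(n_chains)]
  if (is.null(subunits)) {
    subunits <- ifelse(grepl("^[ue]L", chain_names), "60S", "40S")
  } else {
    subunits <- rep_len(subunits, n_chains)
  }

  res_coords <- withr::with_seed(seed, {
    purrr::map(seq_len(n_chains), function(i) {
      jit <- matrix(stats::runif(residues_per_chain * 3, -jitter_r,
                                 jitter_r),
                    ncol = 3)
      sweep(jit, 2, anchors[i, ], `+`)
    })
  })

  # generation-time geometric verification: min inter-chain centroid
  # distance realizes exactly the intended adjacency
  ok <- verify_layout(res_coords, intended, distance_threshold)
  if (!ok) {
    stop_structenrich(
      "layout geometry does not realize the intended contact graph",
      "structenrich_generation_error"
    )
  }

  if (is.null(dir)) dir <- tempfile("toy_complex_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, "toy_complex.pdb")
  write_toy_pdb(pdb_path, chain_ids, res_coords, atoms_per_residue, seed)

  annotation <- tibble(chain_id = chain_ids, protein_name = chain_names,
                       subunit = subunits, paralog_ids = "")
  annotation_path <- file.path(dir, "annotation.tsv")
  readr::write_tsv(annotation, annotation_path, progress = FALSE)

  expected_edges <- tibble(
    from = pmin(chain_names[intended[, 1]], chain_names[intended[, 2]]),
    to = pmax(chain_names[intended[, 1]], chain_names[intended[, 2]])
  ) %>% arrange(.data$from, .data$to)

  list(pdb_path = pdb_path, annotation_path = annotation_path,
       annotation = as_chain_annotation(annotation),
       expected_edges = expected_edges,
       chain_names = chain_names, layout = layout, seed = seed)
}

verify_layout <- function(res_coords, intended, d_t) {
  n <- length(res_coords)
  intended_key <- paste(pmin(intended[, 1], intended[, 2]),
                        pmax(intended[, 1], intended[, 2]))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmin <- min(proxy_cross_dist(res_coords[[i]], res_coords[[j]]))
      touch <- dmin <= d_t
      want <- paste(i, j) %in% intended_key
      if (touch != want) return(FALSE)
    }
  }
  TRUE
}

proxy_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# Write ATOM records via bio3d, one or more atoms per residue. Multi-atom
# residues are jittered then recentered so the geometric centroid equals
# the residue point exactly.
write_toy_pdb <- function(path, chain_ids, res_coords, atoms_per_residue,
                          seed) {
  rows <- withr::with_seed(derive_seed(seed, 7L), {
    purrr::map_dfr(seq_along(chain_ids), function(i) {
      coords <- res_coords[[i]]
      purrr::map_dfr(seq_len(nrow(coords)), function(r) {
        if (atoms_per_residue == 1) {
          xyz <- matrix(coords[r, ], ncol = 3)
        } else {
          jit <- matrix(stats::rnorm(atoms_per_residue * 3, sd = 0.3),
                        ncol = 3)
          jit <- sweep(jit, 2, colMeans(jit))  # recenter: centroid exact
          xyz <- sweep(jit, 2, coords[r, ], `+`)
        }
        tibble(chain = chain_ids[i], resno = r,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               elety = c("CA", paste0("C", seq_len(64)))[
                 seq_len(nrow(xyz))])
      })
    })
  })
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(rows[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(rows)),
    resno = rows$resno,
    resid = rep("GLY", nrow(rows)),
    chain = rows$chain,
    elety = rows$elety,
    o = rep(1, nrow(rows)),
    b = rep(0, nrow(rows))
  )
  path
}

#' Generate a weighted network with a planted heavy module
#'
#' Builds a locally connected background graph (a circulant ring where
#' every node touches its `neighbors` nearest nodes on each side -- the
#' one-dimensional analog of the spatial locality of residue-contact
#' graphs) and plants a fully connected module whose internal edges carry
#' `weight_contrast` times the contact count of every background edge
#' (default 100:1). Random walks entering the module then tend to stay,
#' so region sampling should recover it; the circulant edges crossing the
#' module boundary are the weak bridges.
#'
#' @param n_nodes Total nodes, default 80.
#' @param module_size Planted module size, default 8.
#' @param weight_contrast Intra-module to background contact ratio,
#'   default 100.
#' @param neighbors Background ring neighbors per side, default 2.
#' @param seed Seed recorded on the fixture (topology is deterministic).
#' @return A list: `network` (a `proximity_network`), `module` (character
#'   vector of planted member names).
#' @export
generate_planted_network <- function(n_nodes = 80, module_size = 8,
                                     weight_contrast = 100,
                                     neighbors = 2, seed = 1L) {
  if (module_size >= n_nodes) {
    stop_structenrich("module_size must be < n_nodes",
                      "structenrich_generation_error")
  }
  if (n_nodes <= 2 * neighbors) {
    stop_structenrich("n_nodes must exceed 2 * neighbors",
                      "structenrich_generation_error")
  }
  nodes <- sprintf("P%02d", seq_len(n_nodes))
  module <- nodes[seq_len(module_size)]
  idx <- seq_len(n_nodes)
  circ <- purrr::map_dfr(seq_len(neighbors), function(k) {
    tibble(i = idx, j = ((idx + k - 1) %% n_nodes) + 1)
  })
  mod_pairs <- t(utils::combn(module_size, 2))
  mod <- tibble(from = nodes[mod_pairs[, 1]], to = nodes[mod_pairs[, 2]])
  edges <- circ %>%
    mutate(from = pmin(nodes[.data$i], nodes[.data$j]),
           to = pmax(nodes[.data$i], nodes[.data$j])) %>%
    select(all_of(c("from", "to"))) %>%
    distinct() %>%
    anti_join(mod, by = c("from", "to")) %>%
    mutate(n_contacts = 1L) %>%
    bind_rows(mutate(mod, n_contacts = as.integer(weight_contrast)))
  net <- new_proximity_network(
    tibble(node = nodes), edges,
    weight_mode = "contact_proportion",
    structure_id = sprintf("planted%d", n_nodes)
  )
  list(network = net, module = module, seed = seed)
}

#' Plant an enriched region into binary significance calls
#'
#' Draws independent Bernoulli calls: probability `in_rate` for proteins
#' inside the planted region, `out_rate` outside.
#'
#' @param nodes All protein names.
#' @param region Planted subset of `nodes`.
#' @param in_rate,out_rate Bernoulli rates, `0 <= out_rate < in_rate <= 1`
#'   (equality allowed for null fixtures).
#' @param seed RNG seed.
#' @return Tibble `protein`, `call` with attribute `region`.
#' @export
plant_enriched_region <- function(nodes, region, in_rate = 0.8,
                                  out_rate = 0.1, seed = 1L) {
  if (!all(region %in% nodes)) {
    stop_structenrich("region must be a subset of nodes",
                      "structenrich_validation_error")
  }
  if (out_rate > in_rate) {
    stop_structenrich("out_rate must not exceed in_rate",
                      "structenrich_validation_error")
  }
  calls <- withr::with_seed(seed, {
    p <- ifelse(nodes %in% region, in_rate, out_rate)
    rbinom(length(nodes), 1, p)
  })
  out <- tibble(protein = nodes, call = calls)
  attr(out, "region") <- region
  out
}

#' Generate an abundance fixture with planted 60S:polysome log ratios
#'
#' Simulates label-free quantification abundances for one genotype and
#' temperature across replicates of the 60S and polysome fractions, with
#' multiplicative log-normal noise. Each protein's polysome abundance is
#' its baseline; its 60S abundance is the baseline times
#' `exp(effect)`. Because subunit-sum normalization shifts every ratio by
#' the log ratio of subunit totals, the generator records the analytically
#' expected post-normalization ratio per protein as ground truth.
#'
#' @param n_proteins Number of proteins (all 60S by default).
#' @param effects Numeric vector (recycled) of planted ln-ratio effects on
#'   the raw abundances.
#' @param n_replicates Replicates per fraction, default 4.
#' @param cv Coefficient of variation of the multiplicative noise,
#'   default 0.1.
#' @param genotype,temperature Metadata labels.
#' @param seed RNG seed.
#' @return A list: `abundance` (long tibble for
#'   [normalize_by_subunit()]), `truth` (tibble `protein`,
#'   `planted_effect`, `expected_ln_ratio`, `expected_class`).
#' @export
generate_abundance_fixture <- function(n_proteins = 20, effects = 0,
                                       n_replicates = 4, cv = 0.1,
                                       genotype = "Col-0",
                                       temperature = "10C", seed = 1L) {
  effects <- rep_len(effects, n_proteins)
  proteins <- sprintf("uL%02d", seq_len(n_proteins))
  withr::with_seed(seed, {
    base <- rlnorm(n_proteins, meanlog = log(1e6), sdlog = 0.5)
    mu60 <- base * exp(effects)
    mupoly <- base
    shift <- log(sum(mu60) / sum(mupoly))
    truth <- tibble(
      protein = proteins,
      planted_effect = effects,
      expected_ln_ratio = effects - shift,
      expected_class = classify_ratio(effects - shift)
    )
    sdlog <- sqrt(log(1 + cv^2))
    make_frac <- function(mu, frac) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        tibble(
          protein = proteins, subunit = "60S",
          sample = sprintf("%s_%s_rep%d", frac, temperature, r),
          genotype = genotype, temperature = temperature,
          fraction = frac, replicate = r,
          abundance = mu * rlnorm(n_proteins, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog)
        )
      })
    }
    abundance <- bind_rows(make_frac(mu60, "60S"),
                           make_frac(mupoly, "polysome"))
    list(abundance = abundance, truth = truth, seed = seed)
  })
}
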