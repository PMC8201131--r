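# ggplot2 views of the main result types.

#' Plot a proximity network
#'
#' Fruchterman-Reingold layout (deterministic for a fixed seed); edge
#' width scales with weight, node color with subunit.
#'
#' @param object A `proximity_network`.
#' @param seed Layout seed, default 1.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.proximity_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed,
                         igraph::layout_with_fr(g,
                                                weights = igraph::E(g)$weight))
  nodes <- object$nodes %>%
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges %>%
    left_join(select(nodes, all_of(c("node", "x", "y"))),
              by = c("from" = "node")) %>%
    rename(x_from = "x", y_from = "y") %>%
    left_join(select(nodes, all_of(c("node", "x", "y"))),
              by = c("to" = "node")) %>%
    rename(x_to = "x", y_to = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$y_from,
                   xend = .data$x_to, yend = .data$y_to,
                   linewidth = .data$weight),
      color = "grey60", show.legend = FALSE) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$subunit),
      size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Proximity network: ",
                                 object$structure_id),
                  color = "subunit")
}

#' Plot region enrichment results
#'
#' Bar chart of -log10 p per region, with the Bonferroni-adjusted
#' significance threshold drawn as a dashed line.
#'
#' @param object A `region_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.region_enrichment <- function(object, ...) {
  df <- object$results %>%
    mutate(region_id = factor(.data$region_id,
                              levels = rev(.data$region_id)),
           neglog_p = -log10(pmax(.data$p_value, 1e-300)))
  thr <- -log10(object$alpha / object$m_tests)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog_p,
                                   y = .data$region_id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#4477aa",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10] ~ p),
                  y = NULL,
                  fill = paste0("q < ", object$alpha),
                  title = if (!is.na(object$layer_id))
                    paste0("Spatial enrichment, layer ", object$layer_id)
                  else "Spatial enrichment") +
    ggplot2::theme_minimal()
}

#' Write a molecular-viewer color script
#'
#' Emits PyMOL commands coloring the chains of significant regions
#' (`q < alpha`) one color and everything else another, so enrichment
#' results can be inspected on the 3D structure.
#'
#' @param enrichment A `region_enrichment`.
#' @param structure A `complex_structure` (maps protein names back to
#'   chain ids).
#' @param path Output `.pml` path.
#' @param sig_color,base_color PyMOL color names.
#' @return `path`, invisibly.
#' @export
write_color_script <- function(enrichment, structure, path,
                               sig_color = "blue", base_color = "grey80") {
  stopifnot(inherits(enrichment, "region_enrichment"),
            inherits(structure, "complex_structure"))
  sig_regions <- enrichment$results$region_id[
    enrichment$results$significant]
  sig_proteins <- unique(unlist(enrichment$members[sig_regions]))
  chains <- structure$chains
  sig_chains <- chains$chain_id[chains$protein_name %in% sig_proteins]
  lines <- c(
    sprintf("color %s, all", base_color),
    if (length(sig_chains) > 0)
      sprintf("color %s, chain %s", sig_color,
              paste(sig_chains, collapse = "+")),
    sprintf("# significant regions: %s",
            paste(sig_regions, collapse = " ") %0% "none")
  )
  writeLines(lines, path)
  invisible(path)
}
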