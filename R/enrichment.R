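#' Build the 2x2 contingency table for one region
#'
#' Splits the protein universe (all proteins carrying a binary call;
#' complete-case analysis) by region membership and significance:
#' `a` in-region significant, `b` in-region unchanged, `c` out-of-region
#' significant, `d` out-of-region unchanged. Proteins without a call are
#' excluded from both region and universe counts.
#'
#' @param members Character vector of region member protein names (or a
#'   one-row region tibble with a `members` list-column).
#' @param calls Binary significance calls: a tibble with columns `protein`
#'   and `call` (0/1), or a named 0/1 vector.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
region_contingency <- function(members, calls) {
  if (is.data.frame(members) && "members" %in% names(members)) {
    members <- members$members[[1]]
  }
  calls <- as_binary_calls(calls)
  if (length(members) == 0) {
    stop_structenrich("empty region", "structenrich_degenerate_error")
  }
  in_region <- calls$protein %in% members
  if (!any(in_region)) {
    stop_structenrich("no called protein falls inside the region",
                      "structenrich_degenerate_error")
  }
  sig <- calls$call == 1
  tibble(
    a = sum(in_region & sig),
    b = sum(in_region & !sig),
    c = sum(!in_region & sig),
    d = sum(!in_region & !sig)
  )
}

as_binary_calls <- function(calls) {
  if (!is.data.frame(calls)) {
    calls <- tibble(protein = names(calls), call = unname(calls))
  }
  stopifnot(all(c("protein", "call") %in% names(calls)))
  calls <- as_tibble(calls) %>% filter(!is.na(.data$call))
  if (!all(calls$call %in% c(0, 1))) {
    stop_structenrich("calls must be 0/1", "structenrich_validation_error")
  }
  if (anyDuplicated(calls$protein)) {
    stop_structenrich("duplicated protein in calls",
                      "structenrich_validation_error")
  }
  calls
}

#' Fisher exact test by hypergeometric summation
#'
#' Computes the exact p value of a 2x2 table by direct summation of
#' hypergeometric point probabilities over tables at least as extreme as
#' the observed one, with the margins fixed. `"greater"` (the default,
#' testing enrichment of significant proteins inside the region) sums the
#' upper tail `P(X >= a)`; `"two_sided"` sums all tables whose point
#' probability does not exceed the observed one (up to a 1e-7 relative
#' tolerance, the usual convention).
#'
#' @param a,b,c,d Cell counts (non-negative integers), or pass a one-row
#'   data frame with these columns as `a`.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return The p value.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = c("greater", "two_sided")) {
  if (is.data.frame(a)) {
    tb <- a
    a <- tb$a[1]; b <- tb$b[1]; c <- tb$c[1]; d <- tb$d[1]
  }
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop_structenrich("table cells must be non-negative integers",
                      "structenrich_validation_error")
  }
  k <- a + b          # region size
  K <- a + c          # total significant
  N <- a + b + c + d  # universe
  if (N == 0) return(1)
  lo <- max(0, k - (N - K))
  hi <- min(k, K)
  support <- lo:hi
  probs <- dhyper(support, K, N - K, k)
  if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    obs <- dhyper(a, K, N - K, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
}

#' Bonferroni correction
#'
#' `q_i = min(1, m * p_i)`. `m` defaults to the number of p values but may
#' be larger (e.g. when only a subset of the tested regions is supplied).
#'
#' @param p_values Numeric vector of p values.
#' @param m Number of tests; `m >= 1`.
#' @return Numeric vector of q values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop_structenrich("m must be >= 1", "structenrich_validation_error")
  }
  pmin(1, m * p_values)
}

#' Test every region for enrichment of significant proteins
#'
#' For each region, builds the 2x2 table of the region versus the rest of
#' the called universe, computes the exact Fisher p value, and applies a
#' Bonferroni correction with `m` equal to the number of regions tested in
#' the run. Regions with `q < alpha` are flagged significant.
#'
#' @param regions A `region_set`, or a tibble with `region_id` and a
#'   `members` list-column.
#' @param calls Binary calls (tibble `protein`/`call` or named vector);
#'   see [region_contingency()].
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param alpha Significance threshold on the corrected q value,
#'   default 0.05.
#' @param layer_id Optional label of the omics layer tested (e.g. `"3P"`).
#' @return An object of class `region_enrichment`; `tidy()` returns the
#'   per-region table sorted by p value, `glance()` a one-row summary.
#' @export
enrich_all <- function(regions, calls, alternative = c("greater",
                                                       "two_sided"),
                       alpha = 0.05, layer_id = NA_character_) {
  alternative <- match.arg(alternative)
  run_id <- NULL
  if (inherits(regions, "region_set")) {
    run_id <- regions$run_id
    regions <- regions$regions
  }
  regions <- as_tibble(regions)
  stopifnot("members" %in% names(regions))
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- paste0("region_", seq_len(nrow(regions)))
  }
  calls <- as_binary_calls(calls)
  m <- nrow(regions)
  results <- purrr::map_dfr(seq_len(m), function(i) {
    tb <- region_contingency(regions$members[[i]], calls)
    mutate(tb,
           region_id = regions$region_id[i],
           n_members = length(regions$members[[i]]),
           p_value = fisher_exact(.data$a, .data$b, .data$c, .data$d,
                                  alternative = alternative))
  })
  results <- results %>%
    mutate(q_value = bonferroni(.data$p_value, m),
           significant = .data$q_value < alpha) %>%
    select(all_of(c("region_id", "n_members", "a", "b", "c", "d",
                    "p_value", "q_value", "significant"))) %>%
    arrange(.data$p_value, .data$region_id)
  structure(
    list(results = results, m_tests = m, alternative = alternative,
         alpha = alpha, layer_id = layer_id, run_id = run_id,
         members = setNames(regions$members, regions$region_id)),
    class = "region_enrichment"
  )
}

#' @export
print.region_enrichment <- function(x, ...) {
  cat("<region_enrichment>",
      if (!is.na(x$layer_id)) paste0("layer ", x$layer_id) else "", "\n")
  cat("  regions tested:", x$m_tests,
      "| significant (q <", x$alpha, "):",
      sum(x$results$significant), "\n")
  print(head(x$results, 10))
  invisible(x)
}

#' @rdname enrich_all
#' @param x A `region_enrichment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.region_enrichment <- function(x, ...) {
  x$results %>%
    mutate(layer_id = x$layer_id, run_id = x$run_id %||% NA_character_)
}

#' @rdname enrich_all
#' @exportS3Method generics::glance
glance.region_enrichment <- function(x, ...) {
  tibble(
    n_regions = x$m_tests,
    n_significant = sum(x$results$significant),
    min_p = min(x$results$p_value),
    alternative = x$alternative,
    alpha = x$alpha,
    layer_id = x$layer_id
  )
}

#' Write an enrichment results TSV
#'
#' Mirrors the shape of the per-region report: region families (member
#' proteins), region identifier, p value, Q value and run id; p and Q are
#' additionally given rounded to two decimals for display.
#'
#' @param enrichment A `region_enrichment`.
#' @param path Output path.
#' @param header Extra header lines.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(enrichment, path, header = character()) {
  stopifnot(inherits(enrichment, "region_enrichment"))
  df <- enrichment$results %>%
    mutate(
      protein_families = purrr::map_chr(
        enrichment$members[.data$region_id], paste, collapse = " "),
      run_id = enrichment$run_id %||% "",
      layer_id = enrichment$layer_id,
      p_display = sprintf("%.2f", .data$p_value),
      q_display = sprintf("%.2f", .data$q_value)
    ) %>%
    select(all_of(c("layer_id", "protein_families", "region_id",
                    "p_value", "q_value", "p_display", "q_display",
                    "significant", "run_id")))
  write_tsv_with_header(df, path, header)
}
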