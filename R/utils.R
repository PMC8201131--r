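# Internal helpers shared across modules.

stop_structenrich <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "structenrich_error"), ...)
}

`%0%` <- function(x, y) if (length(x) == 0) y else x

# Canonical unordered edge key: endpoints sorted, joined by "|".
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Format doubles so that read-back reproduces the exact binary value.
format_full <- function(x) sprintf("%.17g", x)

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower) {
    stop_structenrich(
      sprintf("`%s` must be a single finite number >= %s", name, lower),
      "structenrich_validation_error"
    )
  }
  invisible(x)
}

# Derive a child seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i) %% 2147483647L)
}

# Write a TSV with '#'-prefixed header metadata lines, deterministically.
write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_skip_comments <- function(path) {
  if (!file.exists(path)) {
    stop_structenrich(paste0("file not found: ", path), "structenrich_io_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
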