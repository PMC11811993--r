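# Internal validation helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.", name, min,
                  paste(format(x), collapse = ", ")),
          class = "diabaq_invalid_parameter")
  }
  invisible(as.integer(x))
}

stopifnot_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name),
          class = "diabaq_invalid_parameter")
  }
  invisible(as.numeric(x))
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single nonnegative number.", name),
          class = "diabaq_invalid_parameter")
  }
  invisible(as.numeric(x))
}

# Records produced by read_report()/simulate_report() share this shape.
assert_records <- function(records, require_single_gene = FALSE) {
  needed <- c("run_id", "protein_ids", "gene_ids", "stripped_peptide",
              "quantity", "q_value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("Precursor records are missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "diabaq_format_error")
  }
  if (require_single_gene && nrow(records) > 0 &&
      any(lengths(records$gene_ids) != 1L)) {
    abort("Records must carry exactly one gene id; run `filter_multimapped()` first.",
          class = "diabaq_invalid_input")
  }
  invisible(records)
}

# Uniform draws from an inclusive integer range; safe when the range has a
# single value (base::sample() would treat a scalar as 1:n).
resample_int <- function(range, n) {
  if (range[1] == range[2]) {
    rep(as.integer(range[1]), n)
  } else {
    sample(range[1]:range[2], n, replace = TRUE)
  }
}

# Derive a seed stream so independent stages don't reuse the same draws.
substream_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% .Machine$integer.max
}
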