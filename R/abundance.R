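# Abundance tables are long tibbles (gene, column_id, value) with a stage
# tag ("lfq", "ibaq", "binned"), a level tag ("run" or "sample") and a
# col_data tibble describing each column (sample, tissue, dataset labels).
# Missing cells are represented by absent rows.

new_abundance_tbl <- function(tbl, stage, level, col_data = NULL) {
  stopifnot(all(c("gene", "column_id", "value") %in% names(tbl)))
  structure(as_tibble(tbl),
            stage = stage, level = level, col_data = col_data,
            class = c("abundance_tbl", class(as_tibble(tbl))))
}

#' @export
print.abundance_tbl <- function(x, ...) {
  cat(sprintf("<abundance_tbl> stage=%s level=%s: %d genes x %d columns, %d present cells\n",
              abundance_stage(x), attr(x, "level"),
              n_distinct(x$gene), n_distinct(x$column_id), nrow(x)))
  NextMethod()
}

#' Stage and column metadata of an abundance table
#'
#' @param x An abundance table produced by [aggregate_run_abundance()] and
#'   downstream stages.
#' @return `abundance_stage()`: one of `"lfq"`, `"ibaq"`, `"binned"`;
#'   `abundance_col_data()`: a tibble of per-column labels, or `NULL`.
#' @export
abundance_stage <- function(x) attr(x, "stage")

#' @rdname abundance_stage
#' @export
abundance_col_data <- function(x) attr(x, "col_data")

#' Abundance table as a genes-by-columns matrix
#'
#' @param x An abundance table.
#' @return A numeric matrix with genes as rows and runs/samples as columns;
#'   missing cells are `NA`.
#' @export
abundance_matrix <- function(x) {
  wide <- tidyr::pivot_wider(as_tibble(x)[c("gene", "column_id", "value")],
                             names_from = "column_id", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  m
}

#' Median LFQ abundance per gene and MS run
#'
#' Aggregates filtered single-gene precursor records: the cell (gene, run)
#' is the median of that gene's precursor quantities within the run. Pairs
#' without evidence are missing cells.
#'
#' @param records Filtered, single-gene precursor records.
#' @param metadata Optional run-level metadata; when supplied, per-column
#'   sample/tissue/dataset labels are attached.
#' @return An abundance table with `stage = "lfq"`, `level = "run"`.
#' @export
aggregate_run_abundance <- function(records, metadata = NULL) {
  assert_records(records, require_single_gene = TRUE)
  tbl <- as_tibble(records) |>
    mutate(gene = map_chr(.data$gene_ids, 1L)) |>
    group_by(column_id = .data$run_id, .data$gene) |>
    summarise(value = median(.data$quantity), .groups = "drop") |>
    select("gene", "column_id", "value")
  col_data <- NULL
  if (!is.null(metadata)) {
    col_data <- metadata |>
      filter(.data$run_id %in% tbl$column_id) |>
      distinct(column_id = .data$run_id, .data$sample_id, .data$dataset_id,
               .data$tissue, .data$disease_status)
  }
  new_abundance_tbl(tbl, stage = "lfq", level = "run", col_data = col_data)
}

#' Collapse run columns to sample columns
#'
#' The cell (gene, sample) is the median over that sample's runs, ignoring
#' missing cells; it is missing only when the gene is missing in every run
#' of the sample.
#'
#' @param x A run-level abundance table.
#' @param metadata Run-level metadata mapping every run column to a sample.
#' @return An abundance table with the same stage and `level = "sample"`.
#' @export
aggregate_sample_abundance <- function(x, metadata) {
  stopifnot(inherits(x, "abundance_tbl"), attr(x, "level") == "run")
  unmapped <- setdiff(unique(x$column_id), metadata$run_id)
  if (length(unmapped) > 0) {
    abort(sprintf("Run column(s) missing from metadata: %s.",
                  paste(head(unmapped, 3), collapse = ", ")),
          class = "diabaq_mapping_error")
  }
  sample_of <- setNames(metadata$sample_id, metadata$run_id)
  tbl <- as_tibble(x) |>
    mutate(column_id = unname(sample_of[.data$column_id])) |>
    group_by(.data$gene, .data$column_id) |>
    summarise(value = median(.data$value), .groups = "drop")
  col_data <- metadata |>
    filter(.data$sample_id %in% tbl$column_id) |>
    distinct(column_id = .data$sample_id, .data$dataset_id, .data$tissue,
             .data$disease_status)
  new_abundance_tbl(tbl, stage = abundance_stage(x), level = "sample",
                    col_data = col_data)
}

#' Convert LFQ abundances to iBAQ
#'
#' Divides each LFQ value by the gene's theoretical tryptic peptide count.
#' Genes with a zero count cannot receive iBAQ values and are dropped with a
#' warning; genes absent from the count table are an error.
#'
#' @param x An LFQ-stage abundance table.
#' @param counts Output of [count_theoretical_peptides()].
#' @return An abundance table with `stage = "ibaq"`.
#' @export
lfq_to_ibaq <- function(x, counts) {
  stopifnot(inherits(x, "abundance_tbl"))
  if (abundance_stage(x) != "lfq") {
    abort("lfq_to_ibaq() expects an LFQ-stage abundance table.",
          class = "diabaq_invalid_input")
  }
  missing_genes <- setdiff(unique(x$gene), counts$gene)
  if (length(missing_genes) > 0) {
    abort(sprintf("Gene(s) absent from the peptide count table: %s.",
                  paste(head(missing_genes, 3), collapse = ", ")),
          class = "diabaq_consistency_error")
  }
  count_of <- setNames(counts$n_peptides, counts$gene)
  zero <- unique(x$gene)[count_of[unique(x$gene)] == 0L]
  if (length(zero) > 0) {
    warn(sprintf("Dropping %d gene(s) with zero theoretical peptides: %s.",
                 length(zero), paste(head(zero, 3), collapse = ", ")))
  }
  tbl <- as_tibble(x) |>
    filter(!.data$gene %in% zero) |>
    mutate(value = .data$value / unname(count_of[.data$gene]))
  new_abundance_tbl(tbl, stage = "ibaq", level = attr(x, "level"),
                    col_data = abundance_col_data(x))
}

#' Ranked abundance bins
#'
#' Within each column independently, present values are sorted ascending and
#' assigned bins `1..n_bins` of near-equal size (sizes differ by at most
#' one): bin 1 holds the lowest abundances, bin `n_bins` the highest. Ties
#' are broken by stable input order, so the assignment is deterministic, and
#' a larger abundance never receives a lower bin. Missing cells stay
#' missing.
#'
#' @param x An iBAQ-stage abundance table.
#' @param n_bins Number of bins (default 5).
#' @return An abundance table with `stage = "binned"`; values are integers
#'   in `1..n_bins`.
#' @export
bin_abundances <- function(x, n_bins = 5L) {
  stopifnot(inherits(x, "abundance_tbl"))
  n_bins <- stopifnot_count(n_bins, "n_bins", min = 2L)
  short <- as_tibble(x) |> count(.data$column_id) |> filter(.data$n < n_bins)
  if (nrow(short) > 0) {
    abort(sprintf("Column(s) with fewer than %d present values: %s.",
                  n_bins, paste(head(short$column_id, 3), collapse = ", ")),
          class = "diabaq_column_error")
  }
  tbl <- as_tibble(x) |>
    group_by(.data$column_id) |>
    mutate(value = assign_bins(.data$value, n_bins)) |>
    ungroup()
  new_abundance_tbl(tbl, stage = "binned", level = attr(x, "level"),
                    col_data = abundance_col_data(x))
}

# Stable near-equal-size rank binning of one column.
assign_bins <- function(values, n_bins) {
  n <- length(values)
  ord <- order(values) # stable: ties keep input order
  bins <- integer(n)
  bins[ord] <- as.integer(ceiling(seq_len(n) * n_bins / n))
  bins
}

#' @export
autoplot.abundance_tbl <- function(object, ...) {
  df <- as_tibble(object)
  cd <- abundance_col_data(object)
  if (!is.null(cd) && "tissue" %in% names(cd)) {
    ord <- cd$column_id[order(cd$tissue, cd$column_id)]
    df$column_id <- factor(df$column_id, levels = ord)
  }
  p <- ggplot(df, aes(x = .data$column_id, y = .data$gene,
                      fill = .data$value)) +
    geom_tile() +
    labs(x = attr(object, "level"), y = "gene",
         fill = abundance_stage(object)) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  p
}
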