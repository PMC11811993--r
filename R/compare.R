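#' Fraction of missing abundances per tissue and dataset
#'
#' For each tissue within a dataset: `g` is the number of genes with at
#' least one present value among that tissue's `n` samples, and
#' `fm = NA_count / (n * g)` where `NA_count` counts the missing cells of
#' the `g x n` block. A dataset with several tissues is summarised by the
#' median of its tissue `fm` values.
#'
#' @param x A sample-level abundance table with tissue and dataset column
#'   labels.
#' @return A tibble with one row per (dataset, tissue): `dataset_id`,
#'   `tissue`, `n_samples`, `g_genes`, `na_count`, `fm`, plus the dataset
#'   median `fm_dataset`. Tissues with zero identified genes carry `NA` and
#'   are flagged via a warning.
#' @export
missingness_fm <- function(x) {
  stopifnot(inherits(x, "abundance_tbl"))
  cd <- abundance_col_data(x)
  if (is.null(cd) || !all(c("tissue", "dataset_id") %in% names(cd))) {
    abort("Abundance table needs tissue and dataset column labels.",
          class = "diabaq_invalid_input")
  }
  blocks <- cd |> distinct(.data$dataset_id, .data$tissue)
  res <- pmap(blocks, function(dataset_id, tissue) {
    cols <- cd$column_id[cd$dataset_id == dataset_id & cd$tissue == tissue]
    cells <- as_tibble(x) |> filter(.data$column_id %in% cols)
    n <- length(cols)
    g <- n_distinct(cells$gene)
    if (g == 0) {
      warn(sprintf("No identified genes for tissue %s in dataset %s; fm undefined.",
                   tissue, dataset_id))
      return(tibble(dataset_id = dataset_id, tissue = tissue,
                    n_samples = n, g_genes = 0L, na_count = NA_integer_,
                    fm = NA_real_))
    }
    na_count <- n * g - nrow(distinct(cells, .data$gene, .data$column_id))
    tibble(dataset_id = dataset_id, tissue = tissue, n_samples = n,
           g_genes = g, na_count = as.integer(na_count),
           fm = na_count / (n * g))
  }) |>
    list_rbind()
  res |>
    group_by(.data$dataset_id) |>
    mutate(fm_dataset = median(.data$fm, na.rm = TRUE)) |>
    ungroup()
}

#' Pairwise sample correlations on binned abundances
#'
#' For every pair of samples, the squared Pearson correlation of their
#' binned abundances is computed over the proteins commonly identified
#' (present in both samples). Cells with fewer than 3 common genes, or with
#' zero variance in either restricted vector, are undefined (`NA`). The
#' diagonal is 1 wherever a sample has at least two distinct bin values.
#'
#' @param x A binned, sample-level abundance table.
#' @return A `correlation_matrix` tibble in long symmetric form:
#'   `sample_a`, `sample_b`, `n_common`, `r` (signed), `r2`; column labels
#'   are carried in the `"col_data"` attribute.
#' @export
pairwise_binned_correlation <- function(x) {
  stopifnot(inherits(x, "abundance_tbl"))
  if (abundance_stage(x) != "binned") {
    abort("pairwise_binned_correlation() expects a binned abundance table.",
          class = "diabaq_invalid_input")
  }
  m <- abundance_matrix(x)
  samples <- colnames(m)
  pairs <- tidyr::expand_grid(sample_a = samples, sample_b = samples)
  vals <- pmap(pairs, function(sample_a, sample_b) {
    a <- m[, sample_a]
    b <- m[, sample_b]
    common <- !is.na(a) & !is.na(b)
    n_common <- sum(common)
    if (sample_a == sample_b) {
      r <- if (n_common >= 2 && length(unique(a[common])) >= 2) 1 else NA_real_
      return(tibble(n_common = n_common, r = r, r2 = r^2))
    }
    if (n_common < 3 ||
        length(unique(a[common])) < 2 || length(unique(b[common])) < 2) {
      return(tibble(n_common = n_common, r = NA_real_, r2 = NA_real_))
    }
    r <- cor(a[common], b[common], method = "pearson")
    tibble(n_common = n_common, r = r, r2 = r^2)
  }) |>
    list_rbind()
  out <- bind_cols(pairs, vals)
  structure(out, col_data = abundance_col_data(x),
            class = c("correlation_matrix", class(out)))
}

#' Correlation matrix as a square numeric matrix
#'
#' @param x A `correlation_matrix`.
#' @param what Which cell value to place in the matrix (`"r2"` or `"r"`).
#' @return A symmetric samples-by-samples matrix.
#' @export
correlation_matrix <- function(x, what = c("r2", "r")) {
  what <- match.arg(what)
  wide <- tidyr::pivot_wider(as_tibble(x)[c("sample_a", "sample_b", what)],
                             names_from = "sample_b",
                             values_from = dplyr::all_of(what))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_a
  m[, rownames(m), drop = FALSE]
}

#' Median correlation within sample groups
#'
#' Median of the defined off-diagonal `r2` cells whose two samples share a
#' group label: the tissue, or the tissue-within-dataset combination.
#'
#' @param x A `correlation_matrix` from [pairwise_binned_correlation()].
#' @param group_by `"tissue"` or `"tissue_dataset"`.
#' @return A tibble with `group`, `n_samples`, `n_pairs`, `median_r2`.
#'   Groups with fewer than two samples are flagged `NA`.
#' @export
median_group_correlation <- function(x, group_by = c("tissue", "tissue_dataset")) {
  group_by <- match.arg(group_by)
  cd <- attr(x, "col_data")
  if (is.null(cd)) {
    abort("Correlation matrix carries no column labels.",
          class = "diabaq_invalid_input")
  }
  cd$group <- if (group_by == "tissue") {
    cd$tissue
  } else {
    paste(cd$tissue, cd$dataset_id, sep = " / ")
  }
  label_of <- setNames(cd$group, cd$column_id)
  tbl <- as_tibble(x) |>
    mutate(group_a = unname(label_of[.data$sample_a]),
           group_b = unname(label_of[.data$sample_b]))
  cd |>
    group_by(.data$group) |>
    summarise(n_samples = n_distinct(.data$column_id), .groups = "drop") |>
    mutate(stats = map(.data$group, function(g) {
      cells <- tbl |>
        filter(.data$group_a == g, .data$group_b == g,
               .data$sample_a < .data$sample_b, !is.na(.data$r2))
      tibble(n_pairs = nrow(cells),
             median_r2 = if (nrow(cells) == 0) NA_real_ else median(cells$r2))
    })) |>
    tidyr::unnest("stats") |>
    mutate(median_r2 = ifelse(.data$n_samples < 2, NA_real_, .data$median_r2))
}

#' Cross-study abundance comparison per tissue
#'
#' Inner-joins two gene-keyed abundance tables per tissue (only genes
#' quantified in both), optionally log2-transforms the values, and reports
#' the squared Pearson correlation together with the number of joined genes.
#'
#' @param a,b Tibbles with columns `gene`, `tissue`, `abundance` (one value
#'   per gene and tissue, e.g. tissue medians).
#' @param log2_transform Apply `log2` before correlating (default `TRUE`).
#' @return A tibble with `tissue`, `n_genes`, `r`, `r2`; tissues with an
#'   empty join are flagged `NA`.
#' @export
cross_study_compare <- function(a, b, log2_transform = TRUE) {
  needed <- c("gene", "tissue", "abundance")
  if (!all(needed %in% names(a)) || !all(needed %in% names(b))) {
    abort("Both tables need columns gene, tissue, abundance.",
          class = "diabaq_invalid_input")
  }
  tissues <- intersect(unique(a$tissue), unique(b$tissue))
  map(tissues, function(tt) {
    joined <- inner_join(
      a |> filter(.data$tissue == tt) |> select("gene", a_val = "abundance"),
      b |> filter(.data$tissue == tt) |> select("gene", b_val = "abundance"),
      by = "gene"
    ) |>
      filter(!is.na(.data$a_val), !is.na(.data$b_val))
    if (nrow(joined) < 3) {
      return(tibble(tissue = tt, n_genes = nrow(joined),
                    r = NA_real_, r2 = NA_real_))
    }
    av <- joined$a_val
    bv <- joined$b_val
    if (log2_transform) {
      av <- log2(av)
      bv <- log2(bv)
    }
    r <- cor(av, bv, method = "pearson")
    tibble(tissue = tt, n_genes = nrow(joined), r = r, r2 = r^2)
  }) |>
    list_rbind()
}

#' Overlap of two gene sets
#'
#' Counts and percentages for comparing protein inventories of two studies:
#' the intersection and the `a`-only remainder are expressed as percentages
#' of `|a|`, the `b`-only remainder as a percentage of `|b|`, rounded to one
#' decimal place.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return A one-row tibble: `n_a`, `n_b`, `n_common`, `n_a_only`,
#'   `n_b_only`, `pct_common`, `pct_a_only`, `pct_b_only`.
#' @export
#' @examples
#' overlap_summary(c("A", "B", "C"), c("B", "C", "D"))
overlap_summary <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_a <- length(set_a)
  n_b <- length(set_b)
  n_common <- length(intersect(set_a, set_b))
  if (n_a == 0 && n_b == 0) {
    warn("Both sets are empty; percentages undefined.")
  }
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
  tibble(
    n_a = n_a, n_b = n_b, n_common = n_common,
    n_a_only = n_a - n_common, n_b_only = n_b - n_common,
    pct_common = pct(n_common, n_a),
    pct_a_only = pct(n_a - n_common, n_a),
    pct_b_only = pct(n_b - n_common, n_b)
  )
}

#' Protein coverage across tissues and datasets
#'
#' A gene counts as identified in a tissue (or dataset) when it is present
#' in at least one of its samples. Per-tissue and per-dataset counts are
#' reported with their percentage of the overall distinct-gene total (one
#' decimal), together with the number of genes seen in every tissue and in
#' exactly one tissue.
#'
#' @param x A sample-level abundance table with tissue and dataset labels.
#' @return A list of class `coverage_summary`: `total_genes`, `by_tissue`,
#'   `by_dataset`, `n_all_tissues`, `n_single_tissue`.
#' @export
coverage_summary <- function(x) {
  stopifnot(inherits(x, "abundance_tbl"))
  cd <- abundance_col_data(x)
  if (is.null(cd) || !all(c("tissue", "dataset_id") %in% names(cd))) {
    abort("Abundance table needs tissue and dataset column labels.",
          class = "diabaq_invalid_input")
  }
  cells <- as_tibble(x) |>
    left_join(cd, by = "column_id")
  total <- n_distinct(cells$gene)
  by_tissue <- cells |>
    distinct(.data$tissue, .data$gene) |>
    count(.data$tissue, name = "n_genes") |>
    mutate(pct_of_total = round(100 * .data$n_genes / total, 1)) |>
    arrange(dplyr::desc(.data$n_genes))
  by_dataset <- cells |>
    distinct(.data$dataset_id, .data$gene) |>
    count(.data$dataset_id, name = "n_genes") |>
    mutate(pct_of_total = round(100 * .data$n_genes / total, 1)) |>
    arrange(dplyr::desc(.data$n_genes))
  tissues_per_gene <- cells |>
    distinct(.data$gene, .data$tissue) |>
    count(.data$gene, name = "n_tissues")
  n_tissues <- n_distinct(cd$tissue)
  structure(
    list(total_genes = total,
         by_tissue = by_tissue,
         by_dataset = by_dataset,
         n_all_tissues = sum(tissues_per_gene$n_tissues == n_tissues),
         n_single_tissue = sum(tissues_per_gene$n_tissues == 1L)),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("%d distinct genes; %d in all tissues, %d in exactly one tissue\n",
              x$total_genes, x$n_all_tissues, x$n_single_tissue))
  print(x$by_tissue)
  invisible(x)
}

#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- as_tibble(object)
  cd <- attr(object, "col_data")
  if (!is.null(cd) && "tissue" %in% names(cd)) {
    ord <- cd$column_id[order(cd$tissue, cd$column_id)]
    df$sample_a <- factor(df$sample_a, levels = ord)
    df$sample_b <- factor(df$sample_b, levels = ord)
  }
  ggplot(df, aes(x = .data$sample_a, y = .data$sample_b, fill = .data$r2)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = expression(R^2)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5),
                   axis.text.y = ggplot2::element_text(size = 5))
}
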