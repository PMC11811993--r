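#' Database normalizing factor
#'
#' Ratio of target database size to entrapment database size, used to put
#' entrapment (decoy) counts on the scale of the target search space in the
#' cross-dataset FDR estimate.
#'
#' @param target_db_size,entrapment_db_size Sequence counts of the target
#'   and entrapment databases (both >= 1).
#' @return `target_db_size / entrapment_db_size`.
#' @export
#' @examples
#' compute_dn(20838, 41621) # ~0.5
compute_dn <- function(target_db_size, entrapment_db_size) {
  stopifnot_count(target_db_size, "target_db_size")
  stopifnot_count(entrapment_db_size, "entrapment_db_size")
  target_db_size / entrapment_db_size
}

#' Classify protein groups as targets or entrapment decoys
#'
#' Builds one row per distinct protein-group identity (the sorted tuple of
#' gene ids) across datasets. A group is a decoy when every gene id belongs
#' to the entrapment organism; any mixed group counts as a target.
#' `datasets_present` is the number of datasets in which the group has, in
#' at least one MS run, evidence of at least `min_peptides` distinct
#' peptides.
#'
#' @param records Precursor records carrying `dataset_id` (contaminants
#'   should be filtered out first; multi-gene groups are retained since
#'   group identity is the gene tuple).
#' @param entrapment_genes Character vector of entrapment gene ids.
#' @param min_peptides Per-run distinct-peptide evidence threshold
#'   (default 2).
#' @return A `presence_table` tibble: `group_id`, `gene_ids` (list),
#'   `is_decoy`, `datasets_present`.
#' @export
classify_protein_groups <- function(records, entrapment_genes,
                                    min_peptides = 2L) {
  assert_records(records)
  if (!"dataset_id" %in% names(records) || anyNA(records$dataset_id)) {
    abort("Records must carry a dataset_id for cross-dataset classification.",
          class = "diabaq_invalid_input")
  }
  if (any(lengths(records$gene_ids) == 0)) {
    abort("Protein group with empty gene list.",
          class = "diabaq_integrity_error")
  }
  min_peptides <- stopifnot_count(min_peptides, "min_peptides")
  tbl <- as_tibble(records) |>
    mutate(group_id = map_chr(.data$gene_ids,
                              function(g) paste(sort(g), collapse = ";"))) |>
    group_by(.data$dataset_id, .data$run_id, .data$group_id) |>
    summarise(n_pep = n_distinct(.data$stripped_peptide), .groups = "drop") |>
    filter(.data$n_pep >= min_peptides) |>
    distinct(.data$dataset_id, .data$group_id) |>
    count(.data$group_id, name = "datasets_present")
  gene_sets <- lapply(strsplit(tbl$group_id, ";", fixed = TRUE), unique)
  out <- tibble(
    group_id = tbl$group_id,
    gene_ids = gene_sets,
    is_decoy = map_lgl(gene_sets, function(g) all(g %in% entrapment_genes)),
    datasets_present = as.integer(tbl$datasets_present)
  )
  structure(out, class = c("presence_table", class(out)))
}

#' Cross-dataset FDR from entrapment presence counts
#'
#' For each dataset-count threshold `k`, counts the decoy and target groups
#' present in at least `k` datasets and estimates
#' `FDR(k) = dn * decoys_at_k / targets_at_k`. The estimate is reported both
#' raw (`fdr`) and clamped to `[0, 1]` (`fdr_clamped`); it is undefined
#' (flagged `NA`) when no target reaches `k` datasets.
#'
#' @param table A `presence_table` from [classify_protein_groups()].
#' @param dn Database normalizing factor from [compute_dn()].
#' @return An `fdr_table` tibble: `k`, `decoys_at_k`, `targets_at_k`,
#'   `fdr`, `fdr_clamped`; `dn` is stored as an attribute.
#' @export
fdr_at_k <- function(table, dn) {
  if (nrow(table) == 0) {
    abort("Presence table is empty.", class = "diabaq_invalid_input")
  }
  stopifnot_nonneg(dn, "dn")
  if (dn <= 0) {
    abort("`dn` must be positive.", class = "diabaq_invalid_parameter")
  }
  ks <- seq_len(max(table$datasets_present))
  out <- tibble(
    k = as.integer(ks),
    decoys_at_k = vapply(ks, function(k) {
      sum(table$is_decoy & table$datasets_present >= k)
    }, integer(1)),
    targets_at_k = vapply(ks, function(k) {
      sum(!table$is_decoy & table$datasets_present >= k)
    }, integer(1))
  ) |>
    mutate(fdr = ifelse(.data$targets_at_k == 0, NA_real_,
                        dn * .data$decoys_at_k / .data$targets_at_k),
           fdr_clamped = pmin(.data$fdr, 1))
  structure(out, dn = dn, class = c("fdr_table", class(out)))
}

#' Presence histogram of decoy and target groups
#'
#' Counts groups present in exactly `k` datasets, per label. Sums over `k`
#' equal the total numbers of distinct decoy and target groups.
#'
#' @param table A `presence_table` from [classify_protein_groups()].
#' @return A tibble with columns `k`, `decoys`, `targets`.
#' @export
decoy_presence_histogram <- function(table) {
  if (nrow(table) == 0) {
    abort("Presence table is empty.", class = "diabaq_invalid_input")
  }
  tibble(k = seq_len(max(table$datasets_present))) |>
    mutate(
      decoys = vapply(.data$k, function(kk) {
        sum(table$is_decoy & table$datasets_present == kk)
      }, integer(1)),
      targets = vapply(.data$k, function(kk) {
        sum(!table$is_decoy & table$datasets_present == kk)
      }, integer(1))
    )
}

#' @export
tidy.fdr_table <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.fdr_table <- function(x, ...) {
  defined <- !is.na(x$fdr)
  tibble(
    dn = attr(x, "dn"),
    n_decoy_groups = max(x$decoys_at_k),
    n_target_groups = max(x$targets_at_k),
    k_max = max(x$k),
    k_below_1pct = if (any(defined & x$fdr < 0.01)) {
      min(x$k[defined & x$fdr < 0.01])
    } else {
      NA_integer_
    },
    k_below_5pct = if (any(defined & x$fdr < 0.05)) {
      min(x$k[defined & x$fdr < 0.05])
    } else {
      NA_integer_
    }
  )
}

#' @export
autoplot.fdr_table <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$k, y = .data$fdr_clamped)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = c(0.01, 0.05), linetype = "dashed",
               colour = "grey50") +
    labs(x = "present in at least k datasets", y = "estimated FDR") +
    theme_minimal()
}
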