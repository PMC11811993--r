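#' Pipeline configuration
#'
#' Validates and assembles the configuration of a full post-processing run.
#' All referenced paths must exist; validation failures abort before any
#' stage executes.
#'
#' @param report_paths Named character vector: dataset id -> report file.
#' @param fasta_target,fasta_entrapment,fasta_contaminant FASTA paths
#'   (entrapment and contaminant optional, `NULL` to skip).
#' @param sdrf SDRF-like metadata path.
#' @param dialect Report column map from [report_dialect()].
#' @param rules Digestion rules from [digestion_rules()].
#' @param n_bins Number of abundance bins.
#' @param q_value_max Row-level q-value threshold.
#' @param min_peptides Minimum unique peptides per protein per run.
#' @param dn_mode `"exact"` uses the exact database size ratio; `"rounded"`
#'   rounds it to one decimal place.
#' @param status Disease status of samples entering the abundance maps.
#' @param output_dir Directory for written outputs (created if needed);
#'   `NULL` disables writing.
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(report_paths,
                            fasta_target,
                            sdrf,
                            fasta_entrapment = NULL,
                            fasta_contaminant = NULL,
                            dialect = report_dialect(),
                            rules = digestion_rules(),
                            n_bins = 5L,
                            q_value_max = 0.01,
                            min_peptides = 2L,
                            dn_mode = c("exact", "rounded"),
                            status = "normal",
                            output_dir = NULL) {
  dn_mode <- match.arg(dn_mode)
  if (is.null(names(report_paths)) || any(names(report_paths) == "")) {
    abort("`report_paths` must be named by dataset id.",
          class = "diabaq_invalid_parameter")
  }
  paths <- c(report_paths, fasta_target, sdrf, fasta_entrapment,
             fasta_contaminant)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0) {
    abort(sprintf("Input path(s) do not exist: %s.",
                  paste(missing_paths, collapse = ", ")),
          class = "diabaq_invalid_parameter")
  }
  stopifnot_count(n_bins, "n_bins", min = 2L)
  stopifnot_rate(q_value_max, "q_value_max")
  stopifnot_count(min_peptides, "min_peptides")
  structure(
    list(report_paths = report_paths, fasta_target = fasta_target,
         fasta_entrapment = fasta_entrapment,
         fasta_contaminant = fasta_contaminant, sdrf = sdrf,
         dialect = dialect, rules = rules, n_bins = as.integer(n_bins),
         q_value_max = q_value_max, min_peptides = as.integer(min_peptides),
         dn_mode = dn_mode, status = status, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full post-processing pipeline
#'
#' Per dataset: read the report, remove contaminant and multi-mapped
#' evidence, require `min_peptides` unique peptides per protein per run,
#' keep the configured sample status, aggregate precursor medians per run
#' and per sample, convert LFQ to iBAQ and bin. Across datasets: classify
#' protein groups against the entrapment database and estimate FDR(k),
#' compute missingness, coverage and pairwise binned sample correlations.
#' Outputs (when `output_dir` is set) are tab-separated tables plus a
#' machine-readable JSON manifest with per-stage record counts, parameter
#' echo and content hashes; identical config and inputs give identical
#' manifests.
#'
#' @param config A [pipeline_config()] object.
#' @return A list of class `pipeline_result`: `manifest`, `metadata`,
#'   `ibaq` and `binned` sample-level abundance tables, `fdr`
#'   (presence table, FDR table, histogram, dn) when an entrapment database
#'   is configured, `missingness`, `coverage`, `correlations`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  db_target <- read_fasta(config$fasta_target, organism_tag = "target")
  db <- db_target
  db_entrapment <- NULL
  if (!is.null(config$fasta_entrapment)) {
    db_entrapment <- read_fasta(config$fasta_entrapment,
                                organism_tag = "entrapment")
    db <- bind_rows(db, db_entrapment)
  }
  if (!is.null(config$fasta_contaminant)) {
    db <- bind_rows(db, read_fasta(config$fasta_contaminant,
                                   organism_tag = "contaminant",
                                   contaminant = TRUE))
  }
  metadata <- read_sdrf(config$sdrf)

  stage_counts <- list()
  per_dataset <- lapply(names(config$report_paths), function(ds) {
    raw <- read_report(config$report_paths[[ds]], dialect = config$dialect,
                       q_value_max = config$q_value_max, dataset_id = ds)
    no_con <- filter_contaminants(raw, db)
    single <- filter_multimapped(no_con)
    evidenced <- filter_min_unique_peptides(single, config$min_peptides)
    selected <- select_samples(evidenced, metadata, config$status)
    counts <- tibble(
      dataset_id = ds,
      n_rows_raw = nrow(raw),
      n_after_contaminants = nrow(no_con),
      n_after_multimapped = nrow(single),
      n_after_min_peptides = nrow(evidenced),
      n_after_sample_selection = nrow(selected),
      n_unique_peptides = n_distinct(selected$stripped_peptide),
      n_genes = n_distinct(unlist(selected$gene_ids)),
      n_runs = n_distinct(selected$run_id)
    )
    # group classification uses pre-multimap records: group identity is the
    # gene tuple, and mixed target/entrapment groups must stay visible
    list(selected = selected, for_fdr = no_con, counts = counts)
  })
  names(per_dataset) <- names(config$report_paths)

  selected_all <- list_rbind(map(per_dataset, "selected"))
  # abundance maps are built from target-database genes only; entrapment
  # hits feed the FDR estimate, not the quantification
  selected_all <- select_target_genes(selected_all, db_target)
  if (nrow(selected_all) == 0) {
    abort("No records survive filtering; nothing to quantify.",
          class = "diabaq_stage_error")
  }
  run_lfq <- aggregate_run_abundance(selected_all, metadata)
  sample_lfq <- aggregate_sample_abundance(run_lfq, metadata)
  pep_counts <- count_theoretical_peptides(db_target, config$rules)
  sample_ibaq <- lfq_to_ibaq(sample_lfq, pep_counts)
  sample_binned <- bin_abundances(sample_ibaq, config$n_bins)

  fdr <- NULL
  if (!is.null(db_entrapment)) {
    presence <- classify_protein_groups(list_rbind(map(per_dataset, "for_fdr")),
                                        db_entrapment$gene,
                                        config$min_peptides)
    dn <- compute_dn(nrow(db_target), nrow(db_entrapment))
    if (config$dn_mode == "rounded") dn <- round(dn, 1)
    fdr <- list(presence = presence,
                table = fdr_at_k(presence, dn),
                histogram = decoy_presence_histogram(presence),
                dn = dn)
  }

  missingness <- missingness_fm(sample_ibaq)
  coverage <- coverage_summary(sample_ibaq)
  correlations <- pairwise_binned_correlation(sample_binned)

  manifest <- list(
    parameters = list(n_bins = config$n_bins,
                      q_value_max = config$q_value_max,
                      min_peptides = config$min_peptides,
                      dn_mode = config$dn_mode, status = config$status,
                      datasets = names(config$report_paths)),
    stage_counts = list_rbind(map(per_dataset, "counts")),
    n_samples = n_distinct(sample_ibaq$column_id),
    n_genes_quantified = n_distinct(sample_ibaq$gene)
  )

  result <- structure(
    list(manifest = manifest, metadata = metadata, ibaq = sample_ibaq,
         binned = sample_binned, fdr = fdr, missingness = missingness,
         coverage = coverage, correlations = correlations),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    result$manifest$files <- write_pipeline_outputs(result, config$output_dir)
  }
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(dir, name)
  write_wide <- function(x, path) {
    m <- abundance_matrix(x)
    readr::write_tsv(bind_cols(tibble(gene = rownames(m)), as_tibble(m)),
                     path, progress = FALSE)
  }
  write_wide(result$ibaq, out("ibaq_sample_matrix.tsv"))
  write_wide(result$binned, out("binned_sample_matrix.tsv"))
  readr::write_tsv(result$missingness, out("missingness_fm.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(result$correlations),
                   out("sample_correlations.tsv"), progress = FALSE)
  readr::write_tsv(result$coverage$by_tissue, out("coverage_by_tissue.tsv"),
                   progress = FALSE)
  if (!is.null(result$fdr)) {
    readr::write_tsv(as_tibble(result$fdr$table), out("fdr_table.tsv"),
                     progress = FALSE)
    readr::write_tsv(result$fdr$histogram, out("presence_histogram.tsv"),
                     progress = FALSE)
  }
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  hashes <- tibble(file = basename(files),
                   md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(
    list(parameters = result$manifest$parameters,
         stage_counts = result$manifest$stage_counts,
         hashes = hashes),
    out("manifest.json"), auto_unbox = TRUE, digits = NA
  )
  hashes
}

#' Per-dataset quality summary
#'
#' Tabulates, per dataset, the run and sample tallies, surviving precursor
#' rows, unique peptides and unique genes after filtering, the median
#' fraction of missingness, and the study-wide tissue/dataset totals.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return A tibble with one row per dataset.
#' @export
quality_summary <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  meta_counts <- result$metadata |>
    group_by(.data$dataset_id) |>
    summarise(n_runs_design = n_distinct(.data$run_id),
              n_samples_design = n_distinct(.data$sample_id),
              .groups = "drop")
  fm <- result$missingness |>
    distinct(.data$dataset_id, .data$fm_dataset)
  result$manifest$stage_counts |>
    left_join(meta_counts, by = "dataset_id") |>
    left_join(fm, by = "dataset_id")
}

#' @export
print.pipeline_result <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat(sprintf("<pipeline_result> %d dataset(s), %d sample(s), %d gene(s) quantified\n",
              nrow(sc), x$manifest$n_samples, x$manifest$n_genes_quantified))
  print(sc)
  invisible(x)
}
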