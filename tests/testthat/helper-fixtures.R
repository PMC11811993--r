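# Shared desk-scale study configurations and hand-built record fixtures.

tiny_params <- function(...) {
  defaults <- list(
    n_target_genes = 80L, n_entrapment_genes = 40L, n_contaminants = 5L,
    n_datasets = 2L, tissues = c("brain", "liver"),
    samples_per_tissue = 3L, runs_per_sample = 2L, seed = 11L
  )
  do.call(sim_params, modifyList(defaults, list(...)))
}

# A study with every stochastic nuisance switched off: no noise, no dropout,
# no injected artifacts.
noiseless_params <- function(...) {
  tiny_params(lfq_noise_sd = 0, peptide_factor_sd = 0, row_noise_sd = 0,
              dropout_max = 0, decoy_row_rate = 0, multigene_group_rate = 0,
              n_contaminants = 1L, contaminant_rate = 0, ...)
}

# Hand-built precursor records: each argument vectorised over rows; groups
# given as ";"-joined strings for brevity.
make_records <- function(run, genes, peptide, quantity = 100,
                         q_value = 0.001, proteins = NULL, dataset = "DS01") {
  n <- max(length(run), length(genes), length(peptide))
  run <- rep_len(run, n)
  genes <- rep_len(genes, n)
  peptide <- rep_len(peptide, n)
  proteins <- rep_len(proteins %||% paste0("P_", genes), n)
  tibble::tibble(
    run_id = run,
    dataset_id = rep_len(dataset, n),
    protein_ids = strsplit(proteins, ";", fixed = TRUE),
    gene_ids = strsplit(genes, ";", fixed = TRUE),
    stripped_peptide = peptide,
    quantity = rep_len(quantity, n),
    q_value = rep_len(q_value, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an abundance table directly from a genes x columns matrix.
matrix_abundance <- function(m, stage = "ibaq", level = "sample",
                             col_data = NULL) {
  tbl <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "gene"),
    -gene, names_to = "column_id", values_to = "value"
  )
  tbl <- tbl[!is.na(tbl$value), ]
  diabaq:::new_abundance_tbl(tbl, stage = stage, level = level,
                             col_data = col_data)
}
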