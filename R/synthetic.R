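#' Parameters of the synthetic DIA study generator
#'
#' The generator emulates the structure of a multi-dataset human tissue DIA
#' survey: several datasets, each covering one or more tissues, several
#' samples per tissue and repeated MS runs per sample; per-precursor LFQ
#' quantities with multiplicative log-normal noise; protein groups with
#' occasional multi-gene mappings; contaminant entries; entrapment-species
#' decoy groups; and abundance-dependent missingness (logistic dropout in
#' log abundance).
#'
#' Defaults describe a desk-scale study: 3 datasets x 4 tissues x 4 samples
#' x 2 runs, 300 target genes spanning roughly one log10 unit of between-gene
#' dynamic range (`abundance_sdlog = 2.3` on the natural-log scale), 60% of
#' genes expressed in every tissue, and moderate LFQ noise.
#'
#' @param n_target_genes,n_entrapment_genes,n_contaminants Database sizes.
#' @param n_datasets Number of datasets in the study.
#' @param tissues Character vector of tissue labels; every dataset covers
#'   every tissue in the factorial design built by [generate_study_design()].
#' @param samples_per_tissue,runs_per_sample Design depth.
#' @param peptides_per_protein Integer range `c(min, max)`; the number of
#'   tryptic peptides built into each synthetic protein, and the cap on how
#'   many are observed per run.
#' @param abundance_meanlog,abundance_sdlog Natural-log mean and sd of the
#'   per-gene base abundance (arbitrary intensity units).
#' @param tissue_effect_sd Natural-log sd of per-gene, per-tissue deviations
#'   from the base abundance (drives tissue specificity of profiles).
#' @param core_fraction Fraction of target genes expressed in all tissues;
#'   the rest are restricted to a random subset of tissues.
#' @param lfq_noise_sd Natural-log sd of per-sample biological variation.
#' @param peptide_factor_sd Natural-log sd of fixed peptide-specific response
#'   factors (ionization efficiency surrogate).
#' @param row_noise_sd Natural-log sd of per-row technical noise in the report.
#' @param dropout_max,dropout_slope,dropout_quantile Logistic dropout:
#'   a value with abundance `a` goes missing with probability
#'   `dropout_max * plogis(-dropout_slope * (log(a) - log(m)))` where `m` is
#'   the `dropout_quantile` quantile of all true abundances. `dropout_max = 0`
#'   disables dropout.
#' @param decoy_row_rate Expected fraction of emitted protein groups per run
#'   that are entrapment-only decoy groups.
#' @param multigene_group_rate Fraction of emitted target groups whose
#'   protein/gene group lists a second gene id.
#' @param contaminant_rate Per-run probability that each contaminant
#'   accession is observed.
#' @param disease_fraction Fraction of samples labelled "disease" instead of
#'   "normal".
#' @param q_value_max All emitted rows carry q-values at or below this bound.
#' @param seed Integer seed; all generator stages derive their RNG streams
#'   from it.
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_target_genes = 300L,
                       n_entrapment_genes = 150L,
                       n_contaminants = 10L,
                       n_datasets = 3L,
                       tissues = c("brain", "liver", "colon", "skin"),
                       samples_per_tissue = 4L,
                       runs_per_sample = 2L,
                       peptides_per_protein = c(3L, 9L),
                       abundance_meanlog = log(1e6),
                       abundance_sdlog = 2.3,
                       tissue_effect_sd = 1.0,
                       core_fraction = 0.6,
                       lfq_noise_sd = 0.2,
                       peptide_factor_sd = 0.4,
                       row_noise_sd = 0.1,
                       dropout_max = 0.35,
                       dropout_slope = 0.8,
                       dropout_quantile = 0.25,
                       decoy_row_rate = 0.03,
                       multigene_group_rate = 0.02,
                       contaminant_rate = 0.5,
                       disease_fraction = 0,
                       q_value_max = 0.01,
                       seed = 1L) {
  stopifnot_count(n_target_genes, "n_target_genes")
  stopifnot_count(n_entrapment_genes, "n_entrapment_genes")
  stopifnot_count(n_contaminants, "n_contaminants", min = 0L)
  stopifnot_count(n_datasets, "n_datasets")
  stopifnot_count(samples_per_tissue, "samples_per_tissue")
  stopifnot_count(runs_per_sample, "runs_per_sample")
  stopifnot(length(tissues) >= 1, is.character(tissues))
  stopifnot(length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            peptides_per_protein[2] >= peptides_per_protein[1])
  stopifnot_nonneg(abundance_sdlog, "abundance_sdlog")
  stopifnot_nonneg(tissue_effect_sd, "tissue_effect_sd")
  stopifnot_rate(core_fraction, "core_fraction")
  stopifnot_nonneg(lfq_noise_sd, "lfq_noise_sd")
  stopifnot_nonneg(peptide_factor_sd, "peptide_factor_sd")
  stopifnot_nonneg(row_noise_sd, "row_noise_sd")
  stopifnot_rate(dropout_max, "dropout_max")
  stopifnot_nonneg(dropout_slope, "dropout_slope")
  stopifnot_rate(dropout_quantile, "dropout_quantile")
  stopifnot_rate(decoy_row_rate, "decoy_row_rate")
  stopifnot_rate(multigene_group_rate, "multigene_group_rate")
  stopifnot_rate(contaminant_rate, "contaminant_rate")
  stopifnot_rate(disease_fraction, "disease_fraction")
  stopifnot_rate(q_value_max, "q_value_max")
  structure(
    list(n_target_genes = as.integer(n_target_genes),
         n_entrapment_genes = as.integer(n_entrapment_genes),
         n_contaminants = as.integer(n_contaminants),
         n_datasets = as.integer(n_datasets),
         tissues = tissues,
         samples_per_tissue = as.integer(samples_per_tissue),
         runs_per_sample = as.integer(runs_per_sample),
         peptides_per_protein = as.integer(peptides_per_protein),
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         tissue_effect_sd = tissue_effect_sd,
         core_fraction = core_fraction,
         lfq_noise_sd = lfq_noise_sd,
         peptide_factor_sd = peptide_factor_sd,
         row_noise_sd = row_noise_sd,
         dropout_max = dropout_max,
         dropout_slope = dropout_slope,
         dropout_quantile = dropout_quantile,
         decoy_row_rate = decoy_row_rate,
         multigene_group_rate = multigene_group_rate,
         contaminant_rate = contaminant_rate,
         disease_fraction = disease_fraction,
         q_value_max = q_value_max,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Generate a synthetic "one protein sequence per gene" database
#'
#' Each synthetic protein is a concatenation of tryptic peptides: random
#' bodies over the amino-acid alphabet (K/R excluded from bodies, P excluded
#' at peptide starts) terminated by K or R, so that the default digestion
#' rules recover exactly the built-in peptides and every sequence yields at
#' least one observable peptide of length >= 7.
#'
#' @param n_genes Number of genes (one sequence each).
#' @param organism_tag Label stored in the `organism` column and written to
#'   FASTA headers (`OS=`).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param contaminant Mark all entries as contaminants (cRAP-style set).
#' @param peptide_range Integer range `c(min, max)` of peptides per protein.
#' @param prefix Accession/gene id prefix; defaults to the first three
#'   letters of `organism_tag`, upper-cased.
#'
#' @return A tibble with columns `accession`, `gene`, `sequence`,
#'   `organism`, `is_contaminant`.
#' @export
#' @examples
#' db <- generate_sequence_db(5, "human", seed = 1)
#' db$gene
generate_sequence_db <- function(n_genes, organism_tag = "synthetic", seed = 1L,
                                 contaminant = FALSE,
                                 peptide_range = c(3L, 9L),
                                 prefix = NULL) {
  stopifnot_count(n_genes, "n_genes")
  prefix <- prefix %||% toupper(substr(organism_tag, 1, 3))
  body_alphabet <- setdiff(AA_ALPHABET, c("K", "R"))
  start_alphabet <- setdiff(body_alphabet, "P")
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_genes), function(i) {
      n_pep <- sample(peptide_range[1]:peptide_range[2], 1L)
      peps <- vapply(seq_len(n_pep), function(j) {
        len <- sample(7:24, 1L) # body + terminal K/R stays within 7..30
        body <- c(sample(start_alphabet, 1L),
                  sample(body_alphabet, len - 2L, replace = TRUE))
        paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
      }, character(1))
      paste(peps, collapse = "")
    }, character(1))
  })
  tibble(
    accession = sprintf("%s%05d", prefix, seq_len(n_genes)),
    gene = sprintf("%s_G%04d", prefix, seq_len(n_genes)),
    sequence = seqs,
    organism = organism_tag,
    is_contaminant = isTRUE(contaminant)
  )
}

#' Factorial study design
#'
#' Builds run-level sample metadata: every dataset covers every tissue with
#' `samples_per_tissue` samples and `runs_per_sample` MS runs per sample, so
#' the total run count is
#' `n_datasets * length(tissues) * samples_per_tissue * runs_per_sample`.
#' A `disease_fraction` of samples (chosen deterministically under the seed)
#' is labelled "disease"; the rest are "normal".
#'
#' @param params A [sim_params()] object.
#'
#' @return A tibble with one row per MS run: `run_id`, `sample_id`,
#'   `dataset_id`, `tissue`, `disease_status`.
#' @export
generate_study_design <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  design <- tidyr::expand_grid(
    dataset_id = sprintf("DS%02d", seq_len(params$n_datasets)),
    tissue = params$tissues,
    sample_ix = seq_len(params$samples_per_tissue)
  ) |>
    mutate(sample_id = sprintf("%s_%s_S%02d", .data$dataset_id,
                               gsub("[^A-Za-z0-9]+", "", .data$tissue),
                               .data$sample_ix))
  n_samples <- nrow(design)
  n_disease <- round(params$disease_fraction * n_samples)
  disease_ix <- withr::with_seed(substream_seed(params$seed, 1L),
                                 sample(n_samples, n_disease))
  design$disease_status <- "normal"
  design$disease_status[disease_ix] <- "disease"
  design |>
    tidyr::expand_grid(run_ix = seq_len(params$runs_per_sample)) |>
    mutate(run_id = sprintf("%s_R%d.raw", .data$sample_id, .data$run_ix)) |>
    select("run_id", "sample_id", "dataset_id", "tissue", "disease_status")
}

#' Study design from per-dataset run and sample counts
#'
#' Builds run-level metadata from an explicit table of datasets, their
#' tissue, and their sample and run counts (the shape in which published
#' multi-dataset reanalyses tabulate their designs). Runs are distributed
#' across samples as evenly as possible.
#'
#' @param counts A tibble with columns `dataset_id`, `tissue`, `n_samples`,
#'   `n_runs` (with `n_runs >= n_samples`).
#' @param disease_status Status label applied to every sample.
#'
#' @return Run-level metadata tibble, as in [generate_study_design()].
#' @export
#' @examples
#' design <- study_design_from_counts(tissue_atlas_design())
#' length(unique(design$run_id))    # 356
#' length(unique(design$sample_id)) # 178
study_design_from_counts <- function(counts, disease_status = "normal") {
  needed <- c("dataset_id", "tissue", "n_samples", "n_runs")
  if (!all(needed %in% names(counts))) {
    abort("`counts` needs columns dataset_id, tissue, n_samples, n_runs.",
          class = "diabaq_invalid_parameter")
  }
  if (any(counts$n_runs < counts$n_samples)) {
    abort("Each dataset needs at least one run per sample.",
          class = "diabaq_invalid_parameter")
  }
  pmap(counts[needed], function(dataset_id, tissue, n_samples, n_runs) {
    # distribute runs over samples with sizes differing by at most one
    runs_per <- rep(n_runs %/% n_samples, n_samples)
    extra <- n_runs %% n_samples
    if (extra > 0) runs_per[seq_len(extra)] <- runs_per[seq_len(extra)] + 1L
    sample_ids <- sprintf("%s_%s_S%02d", dataset_id,
                          gsub("[^A-Za-z0-9]+", "", tissue), seq_len(n_samples))
    tibble(
      sample_id = rep(sample_ids, runs_per),
      run_ix = unlist(lapply(runs_per, seq_len)),
      dataset_id = dataset_id,
      tissue = tissue
    )
  }) |>
    list_rbind() |>
    mutate(run_id = sprintf("%s_R%d.raw", .data$sample_id, .data$run_ix),
           disease_status = disease_status) |>
    select("run_id", "sample_id", "dataset_id", "tissue", "disease_status")
}

#' Design table of a 15-dataset human tissue DIA survey
#'
#' Per-dataset MS-run and healthy/normal sample counts of a public
#' 15-dataset, 12-tissue human DIA reanalysis (356 runs, 178 samples in
#' total), usable with [study_design_from_counts()] to reproduce that study
#' design at the metadata level.
#'
#' @return A tibble with columns `dataset_id`, `tissue`, `n_samples`, `n_runs`.
#' @export
tissue_atlas_design <- function() {
  tibble(
    dataset_id = sprintf("DS%02d", 1:15),
    tissue = c("brain", "colon", "duodenum", "esophagus", "heart", "liver",
               "lung", "pancreas", "skin", "thyroid", "brain", "brain",
               "breast epithelium", "skin", "skeletal muscle"),
    n_runs = c(75L, 19L, 6L, 3L, 10L, 33L, 8L, 25L, 10L, 8L, 71L, 17L, 4L,
               13L, 54L),
    n_samples = c(19L, 19L, 6L, 3L, 10L, 11L, 4L, 25L, 10L, 8L, 11L, 17L,
                  4L, 13L, 18L)
  )
}

#' Simulate ground-truth protein abundances
#'
#' Draws one mean log-abundance per gene and tissue (a shared base level plus
#' a tissue effect), restricts a `1 - core_fraction` share of genes to random
#' tissue subsets, and adds per-sample log-normal variation. With
#' `lfq_noise_sd = 0` all samples of a tissue share identical abundances.
#'
#' @param db Target sequence database tibble.
#' @param design Run-level metadata from [generate_study_design()].
#' @param params A [sim_params()] object.
#'
#' @return An object of class `ground_truth`: a list with `abundance`
#'   (genes x samples matrix; `NA` marks genes absent from the sample's
#'   tissue profile), `tissue_profile` (genes x tissues matrix of tissue
#'   means), `design`, and `core_genes`.
#' @export
simulate_true_abundances <- function(db, design, params = sim_params()) {
  if (nrow(db) == 0 || nrow(design) == 0) {
    abort("Sequence database and study design must be nonempty.",
          class = "diabaq_invalid_input")
  }
  genes <- db$gene
  tissues <- unique(design$tissue)
  samples <- distinct(design, .data$sample_id, .data$tissue)
  withr::with_seed(substream_seed(params$seed, 2L), {
    base_log <- rnorm(length(genes), params$abundance_meanlog,
                      params$abundance_sdlog)
    effect <- matrix(rnorm(length(genes) * length(tissues), 0,
                           params$tissue_effect_sd),
                     nrow = length(genes),
                     dimnames = list(genes, tissues))
    n_core <- round(params$core_fraction * length(genes))
    core <- sort(sample(length(genes), n_core))
    present <- matrix(TRUE, length(genes), length(tissues),
                      dimnames = list(genes, tissues))
    restricted <- setdiff(seq_along(genes), core)
    for (g in restricted) {
      k <- sample(seq_len(max(1L, ceiling(length(tissues) / 2))), 1L)
      keep <- sample(length(tissues), k)
      present[g, -keep] <- FALSE
    }
    profile <- exp(base_log + effect)
    profile[!present] <- NA_real_
    noise <- matrix(rnorm(length(genes) * nrow(samples), 0,
                          params$lfq_noise_sd),
                    nrow = length(genes))
    abundance <- profile[, samples$tissue, drop = FALSE] * exp(noise)
    colnames(abundance) <- samples$sample_id
  })
  structure(
    list(abundance = abundance,
         tissue_profile = profile,
         design = design,
         core_genes = genes[core]),
    class = "ground_truth"
  )
}
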