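#' Simulate a DIA-NN-style precursor report
#'
#' For every MS run in the design and every gene of the run's tissue profile
#' that survives abundance-dependent dropout, one row per observed peptide is
#' emitted. Peptide sequences come from the gene's true tryptic digest; the
#' number observed is drawn from `peptides_per_protein` and capped at the
#' digest size. Row quantities are
#' `true abundance x peptide-specific factor x log-normal noise`.
#' The simulator also injects (a) contaminant-accession rows, (b)
#' entrapment-only protein groups at `decoy_row_rate` of emitted groups,
#' and (c) two-gene protein groups at `multigene_group_rate`. All rows carry
#' q-values at or below `q_value_max`.
#'
#' @param truth A `ground_truth` object from [simulate_true_abundances()].
#' @param db Target sequence database; every ground-truth gene must be
#'   present in it.
#' @param params A [sim_params()] object.
#' @param db_entrapment,db_contaminant Optional entrapment / contaminant
#'   databases; omit (NULL) to disable the corresponding injection.
#'
#' @return A tibble of precursor records (`run_id`, `dataset_id`,
#'   `protein_ids`, `gene_ids`, `stripped_peptide`, `quantity`, `q_value`;
#'   group columns are list-columns of character vectors). The attribute
#'   `"injection_log"` records, per run, emitted target-group, decoy-group,
#'   multi-gene-group and contaminant-row counts, and the attribute
#'   `"decoy_genes"` the distinct entrapment genes injected.
#' @export
simulate_report <- function(truth, db, params = sim_params(),
                            db_entrapment = NULL, db_contaminant = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  missing_genes <- setdiff(rownames(truth$abundance), db$gene)
  if (length(missing_genes) > 0) {
    abort(sprintf("Ground-truth gene(s) absent from the database: %s.",
                  paste(head(missing_genes, 3), collapse = ", ")),
          class = "diabaq_consistency_error")
  }
  design <- truth$design
  abundance <- truth$abundance
  genes <- rownames(abundance)
  rules <- digestion_rules()
  digests <- lapply(setNames(db$sequence, db$gene)[genes], digest_tryptic,
                    rules = rules)
  digest_len <- lengths(digests)
  acc_of_gene <- setNames(db$accession, db$gene)

  ent_digests <- NULL
  if (!is.null(db_entrapment) && nrow(db_entrapment) > 0) {
    ent_digests <- lapply(setNames(db_entrapment$sequence, db_entrapment$gene),
                          digest_tryptic, rules = rules)
    ent_acc <- setNames(db_entrapment$accession, db_entrapment$gene)
  }
  con_digests <- NULL
  if (!is.null(db_contaminant) && nrow(db_contaminant) > 0) {
    con_digests <- lapply(setNames(db_contaminant$sequence,
                                   db_contaminant$gene),
                          digest_tryptic, rules = rules)
    con_acc <- setNames(db_contaminant$accession, db_contaminant$gene)
  }

  pep_range <- params$peptides_per_protein
  dropout_mid <- if (params$dropout_max > 0) {
    log(quantile(abundance, params$dropout_quantile, na.rm = TRUE, names = FALSE))
  } else {
    0
  }

  withr::with_seed(substream_seed(params$seed, 3L), {
    # peptide response factors, fixed per (gene, peptide) across the study
    factors <- lapply(digests, function(p) {
      setNames(exp(rnorm(length(p), 0, params$peptide_factor_sd)), p)
    })

    per_run <- lapply(seq_len(nrow(design)), function(ri) {
      run <- design$run_id[ri]
      ds <- design$dataset_id[ri]
      ab <- abundance[, design$sample_id[ri]]
      present <- which(!is.na(ab))
      if (params$dropout_max > 0 && length(present) > 0) {
        p_miss <- params$dropout_max *
          plogis(-params$dropout_slope * (log(ab[present]) - dropout_mid))
        present <- present[runif(length(present)) > p_miss]
      }
      if (length(present) > 0) {
        n_obs <- pmin(resample_int(pep_range, length(present)),
                      digest_len[present])
        obs_list <- lapply(seq_along(present), function(i) {
          peps <- digests[[present[i]]]
          if (length(peps) == n_obs[i]) peps else sample(peps, n_obs[i])
        })
        pep_vec <- unlist(obs_list, use.names = FALSE)
        fac_vec <- unlist(lapply(seq_along(present), function(i) {
          factors[[present[i]]][obs_list[[i]]]
        }), use.names = FALSE)
        rows <- tibble(
          gene = rep(genes[present], lengths(obs_list)),
          stripped_peptide = pep_vec,
          quantity = rep(unname(ab[present]), lengths(obs_list)) *
            unname(fac_vec) *
            exp(rnorm(length(pep_vec), 0, params$row_noise_sd))
        )
      } else {
        rows <- tibble(gene = character(0), stripped_peptide = character(0),
                       quantity = numeric(0))
      }
      n_target_groups <- if (nrow(rows) > 0) n_distinct(rows$gene) else 0L

      # multi-gene groups: a second target gene id appended to the group
      multi_genes <- character(0)
      if (params$multigene_group_rate > 0 && n_target_groups > 1) {
        emitted <- unique(rows$gene)
        pick <- runif(length(emitted)) < params$multigene_group_rate
        multi_genes <- emitted[pick]
        partner <- vapply(multi_genes, function(g) {
          sample(setdiff(genes, g), 1L)
        }, character(1))
        names(partner) <- multi_genes
      }
      if (nrow(rows) > 0) {
        rows$gene_ids <- lapply(rows$gene, function(g) {
          if (g %in% multi_genes) sort(c(g, partner[[g]])) else g
        })
        rows$protein_ids <- lapply(rows$gene_ids, function(gs) {
          unname(acc_of_gene[gs])
        })
      } else {
        rows$gene_ids <- list()
        rows$protein_ids <- list()
      }

      # entrapment-only decoy groups
      decoy_rows <- NULL
      decoy_genes_run <- character(0)
      if (!is.null(ent_digests) && params$decoy_row_rate > 0 &&
          n_target_groups > 0) {
        r <- params$decoy_row_rate
        n_decoys <- rbinom(1L, n_target_groups, r / (1 - r))
        n_decoys <- min(n_decoys, length(ent_digests))
        if (n_decoys > 0) {
          decoy_genes_run <- sample(names(ent_digests), n_decoys)
          decoy_rows <- list_rbind(lapply(decoy_genes_run, function(g) {
            peps <- ent_digests[[g]]
            n_obs <- min(max(2L, resample_int(pep_range, 1L)),
                         length(peps))
            obs <- if (length(peps) == 1L) peps else sample(peps, n_obs)
            q <- exp(rnorm(length(obs), params$abundance_meanlog,
                           params$abundance_sdlog))
            tibble(gene = g, stripped_peptide = obs, quantity = q,
                   gene_ids = as.list(rep(g, length(obs))),
                   protein_ids = as.list(rep(unname(ent_acc[g]), length(obs))))
          }))
        }
      }

      # contaminant rows
      con_rows <- NULL
      if (!is.null(con_digests) && params$contaminant_rate > 0) {
        seen <- names(con_digests)[runif(length(con_digests)) <
                                     params$contaminant_rate]
        if (length(seen) > 0) {
          con_rows <- list_rbind(lapply(seen, function(g) {
            peps <- con_digests[[g]]
            n_obs <- min(sample(3L, 1L), length(peps))
            obs <- if (length(peps) == 1L) peps else sample(peps, n_obs)
            q <- exp(rnorm(length(obs), params$abundance_meanlog,
                           params$abundance_sdlog))
            tibble(gene = g, stripped_peptide = obs, quantity = q,
                   gene_ids = as.list(rep(g, length(obs))),
                   protein_ids = as.list(rep(unname(con_acc[g]), length(obs))))
          }))
        }
      }

      all_rows <- bind_rows(rows, decoy_rows, con_rows)
      if (nrow(all_rows) == 0) {
        return(list(records = NULL,
                    log = tibble(run_id = run, dataset_id = ds,
                                 n_rows = 0L, n_target_groups = 0L,
                                 n_decoy_groups = 0L, n_multigene_groups = 0L,
                                 n_multigene_rows = 0L,
                                 n_contaminant_rows = 0L),
                    decoy_genes = character(0)))
      }
      all_rows$q_value <- runif(nrow(all_rows), 0, params$q_value_max)
      records <- tibble(
        run_id = run,
        dataset_id = ds,
        protein_ids = all_rows$protein_ids,
        gene_ids = all_rows$gene_ids,
        stripped_peptide = all_rows$stripped_peptide,
        quantity = all_rows$quantity,
        q_value = all_rows$q_value
      )
      list(records = records,
           log = tibble(run_id = run, dataset_id = ds,
                        n_rows = nrow(records),
                        n_target_groups = n_target_groups,
                        n_decoy_groups = length(decoy_genes_run),
                        n_multigene_groups = length(multi_genes),
                        n_multigene_rows = sum(lengths(records$gene_ids) > 1L),
                        n_contaminant_rows = if (is.null(con_rows)) 0L else nrow(con_rows)),
           decoy_genes = decoy_genes_run)
    })
  })

  records <- list_rbind(keep(map(per_run, "records"), Negate(is.null)))
  log <- list_rbind(map(per_run, "log"))
  structure(records,
            injection_log = log,
            decoy_genes = sort(unique(unlist(map(per_run, "decoy_genes")))))
}

#' Simulate a complete synthetic DIA study
#'
#' Convenience wrapper building the three sequence databases (target,
#' entrapment, contaminant), the factorial study design, ground-truth
#' abundances and the precursor report in one call.
#'
#' @param params A [sim_params()] object.
#'
#' @return A list with `params`, `db_target`, `db_entrapment`,
#'   `db_contaminant`, `db` (all three combined), `design`, `truth`,
#'   `report`.
#' @export
#' @examples
#' study <- simulate_study(sim_params(n_target_genes = 50, n_datasets = 1,
#'                                    tissues = c("brain", "liver")))
#' nrow(study$report)
simulate_study <- function(params = sim_params()) {
  db_target <- generate_sequence_db(params$n_target_genes, "human",
                                    seed = substream_seed(params$seed, 11L),
                                    prefix = "HUM",
                                    peptide_range = params$peptides_per_protein)
  db_entrapment <- generate_sequence_db(params$n_entrapment_genes,
                                        "arabidopsis",
                                        seed = substream_seed(params$seed, 12L),
                                        prefix = "ATH",
                                        peptide_range = params$peptides_per_protein)
  db_contaminant <- if (params$n_contaminants > 0) {
    generate_sequence_db(params$n_contaminants, "contaminant",
                         seed = substream_seed(params$seed, 13L),
                         contaminant = TRUE, prefix = "CON")
  } else {
    NULL
  }
  design <- generate_study_design(params)
  truth <- simulate_true_abundances(db_target, design, params)
  report <- simulate_report(truth, db_target, params,
                            db_entrapment = db_entrapment,
                            db_contaminant = db_contaminant)
  list(params = params,
       db_target = db_target,
       db_entrapment = db_entrapment,
       db_contaminant = db_contaminant,
       db = bind_rows(db_target, db_entrapment, db_contaminant),
       design = design,
       truth = truth,
       report = report)
}

#' Write precursor records as a DIA-NN-style report
#'
#' Emits the minimal column set consumed by [read_report()]: `Run`,
#' `Protein.Group`, `Genes`, `Stripped.Sequence`, `Precursor.Quantity`,
#' `Q.Value`, `PG.Q.Value`. Multi-member groups are joined with ";".
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param records Precursor record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  assert_records(records)
  out <- tibble(
    Run = records$run_id,
    Protein.Group = map_chr(records$protein_ids, paste, collapse = ";"),
    Genes = map_chr(records$gene_ids, paste, collapse = ";"),
    Stripped.Sequence = records$stripped_peptide,
    Precursor.Quantity = sprintf("%.17g", records$quantity),
    Q.Value = sprintf("%.17g", records$q_value),
    PG.Q.Value = sprintf("%.17g", records$q_value)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a sequence database as FASTA
#'
#' Headers follow the `accession GN=gene OS=organism` convention parsed by
#' [read_fasta()].
#'
#' @param db Sequence database tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  seqs <- Biostrings::AAStringSet(setNames(
    db$sequence,
    sprintf("%s GN=%s OS=%s", db$accession, db$gene, db$organism)
  ))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write run-level metadata as an SDRF-like table
#'
#' One row per data file, with the column set consumed by [read_sdrf()]:
#' `source name`, `characteristics[organism part]`,
#' `characteristics[disease]`, `comment[data file]`, `comment[dataset id]`.
#'
#' @param design Run-level metadata tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdrf <- function(design, path) {
  out <- tibble(
    `source name` = design$sample_id,
    `characteristics[organism part]` = design$tissue,
    `characteristics[disease]` = design$disease_status,
    `comment[data file]` = design$run_id,
    `comment[dataset id]` = design$dataset_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
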