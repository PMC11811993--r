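#' Column-name map for DIA-NN-style reports
#'
#' Report column names drift across search-engine versions; the dialect maps
#' the fields the post-processing needs onto the column names found in the
#' file. The default matches DIA-NN 1.8.x main reports.
#'
#' @param run,protein_group,gene_group,stripped_peptide,quantity,q_value
#'   Column names in the report file.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_report()].
#' @export
report_dialect <- function(run = "Run",
                           protein_group = "Protein.Group",
                           gene_group = "Genes",
                           stripped_peptide = "Stripped.Sequence",
                           quantity = "Precursor.Quantity",
                           q_value = "Q.Value") {
  c(run = run, protein_group = protein_group, gene_group = gene_group,
    stripped_peptide = stripped_peptide, quantity = quantity,
    q_value = q_value)
}

#' Read a DIA-NN-style precursor report
#'
#' Parses the tab-separated report into one record per row, splitting
#' multi-member protein and gene groups on `";"`, and drops rows whose
#' q-value exceeds `q_value_max` (reported via a message). Since the search
#' engine itself is not run here, this threshold reproduces the per-run
#' q-value cutoff a search would have applied.
#'
#' @param path Report file path.
#' @param dialect Column-name map from [report_dialect()].
#' @param q_value_max Row-level q-value threshold (default 0.01).
#' @param dataset_id Optional dataset label attached to every record (when
#'   reports are organised one file per dataset).
#'
#' @return A tibble of precursor records with columns `run_id`,
#'   `dataset_id`, `protein_ids` (list), `gene_ids` (list),
#'   `stripped_peptide`, `quantity`, `q_value`.
#' @export
read_report <- function(path, dialect = report_dialect(), q_value_max = 0.01,
                        dataset_id = NA_character_) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Report %s is missing required column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")),
          class = "diabaq_format_error")
  }
  quantity <- suppressWarnings(as.numeric(raw[[dialect[["quantity"]]]]))
  bad <- which(is.na(quantity) & !is.na(raw[[dialect[["quantity"]]]]))
  if (nrow(raw) > 0 && (anyNA(quantity) || length(bad) > 0)) {
    bad <- union(bad, which(is.na(quantity)))
    abort(sprintf("Unparseable quantity in %s at data row(s): %s.",
                  path, paste(head(sort(bad), 5), collapse = ", ")),
          class = "diabaq_format_error")
  }
  q_value <- suppressWarnings(as.numeric(raw[[dialect[["q_value"]]]]))
  records <- tibble(
    run_id = raw[[dialect[["run"]]]],
    dataset_id = dataset_id,
    protein_ids = strsplit(raw[[dialect[["protein_group"]]]], ";", fixed = TRUE),
    gene_ids = strsplit(raw[[dialect[["gene_group"]]]], ";", fixed = TRUE),
    stripped_peptide = raw[[dialect[["stripped_peptide"]]]],
    quantity = quantity,
    q_value = q_value
  )
  keep_row <- records$q_value <= q_value_max
  n_drop <- sum(!keep_row)
  if (n_drop > 0) {
    inform(sprintf("Dropped %d row(s) with q-value > %g.", n_drop, q_value_max))
  }
  records[keep_row, ]
}

#' Read a protein sequence database from FASTA
#'
#' Accessions are taken from the first whitespace-delimited header token;
#' gene ids from a `GN=` field when present, otherwise the accession is
#' reused. Duplicate accessions and empty sequences are integrity errors.
#'
#' @param path FASTA file path.
#' @param organism_tag Organism label stored with every entry (overridden by
#'   an `OS=` header field when present).
#' @param contaminant Flag all entries as contaminants.
#'
#' @return A sequence database tibble (`accession`, `gene`, `sequence`,
#'   `organism`, `is_contaminant`).
#' @export
read_fasta <- function(path, organism_tag = "unknown", contaminant = FALSE) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- stringr::str_extract(headers, "^\\S+")
  if (anyDuplicated(accession)) {
    abort(sprintf("Duplicate accession(s) in %s: %s.", path,
                  paste(head(unique(accession[duplicated(accession)]), 3),
                        collapse = ", ")),
          class = "diabaq_integrity_error")
  }
  sequence <- as.character(seqs)
  if (any(nchar(sequence) == 0)) {
    abort(sprintf("Empty sequence(s) in %s (e.g. %s).", path,
                  accession[which(nchar(sequence) == 0)[1]]),
          class = "diabaq_integrity_error")
  }
  gene <- stringr::str_match(headers, "GN=(\\S+)")[, 2]
  gene <- ifelse(is.na(gene), accession, gene)
  os <- stringr::str_match(headers, "OS=(\\S+)")[, 2]
  tibble(
    accession = accession,
    gene = gene,
    sequence = unname(sequence),
    organism = ifelse(is.na(os), organism_tag, os),
    is_contaminant = isTRUE(contaminant)
  )
}

#' Read SDRF-like sample metadata
#'
#' Expects a tab-separated table with one row per data file and the columns
#' `source name`, `characteristics[organism part]`,
#' `characteristics[disease]`, `comment[data file]`, `comment[dataset id]`.
#' Every data file must belong to exactly one sample.
#'
#' @param path Metadata file path.
#' @return Run-level metadata tibble (`run_id`, `sample_id`, `dataset_id`,
#'   `tissue`, `disease_status`).
#' @export
read_sdrf <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("source name", "characteristics[organism part]",
              "characteristics[disease]", "comment[data file]",
              "comment[dataset id]")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("SDRF %s is missing required column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "diabaq_format_error")
  }
  meta <- tibble(
    run_id = raw[["comment[data file]"]],
    sample_id = raw[["source name"]],
    dataset_id = raw[["comment[dataset id]"]],
    tissue = raw[["characteristics[organism part]"]],
    disease_status = raw[["characteristics[disease]"]]
  )
  dup <- meta |>
    distinct(.data$run_id, .data$sample_id) |>
    count(.data$run_id) |>
    filter(.data$n > 1)
  if (anyDuplicated(meta$run_id) || nrow(dup) > 0) {
    bad <- unique(meta$run_id[duplicated(meta$run_id)])
    abort(sprintf("Data file(s) listed more than once in %s: %s.", path,
                  paste(head(c(dup$run_id, bad), 3), collapse = ", ")),
          class = "diabaq_integrity_error")
  }
  meta
}

#' Remove contaminant evidence
#'
#' Drops every record whose protein group contains at least one contaminant
#' accession — conservative: a group sharing evidence with a contaminant is
#' treated as contaminated ambiguous evidence.
#'
#' @param records Precursor record tibble.
#' @param db Sequence database with `is_contaminant` flags.
#' @return Surviving records; the number removed is reported via a message
#'   and stored in the `"n_removed"` attribute.
#' @export
filter_contaminants <- function(records, db) {
  assert_records(records)
  contaminants <- db$accession[db$is_contaminant]
  keep_row <- !map_lgl(records$protein_ids, function(p) any(p %in% contaminants))
  n_removed <- sum(!keep_row)
  inform(sprintf("filter_contaminants: removed %d record(s).", n_removed))
  structure(records[keep_row, ], n_removed = n_removed)
}

#' Remove multi-mapped evidence
#'
#' Drops records whose protein group or gene group lists more than one
#' identifier, so that each surviving record maps one peptide observation to
#' exactly one canonical protein (gene).
#'
#' @param records Precursor record tibble.
#' @return Surviving records, with the removal count in `"n_removed"`.
#' @export
filter_multimapped <- function(records) {
  assert_records(records)
  keep_row <- lengths(records$protein_ids) == 1L & lengths(records$gene_ids) == 1L
  n_removed <- sum(!keep_row)
  inform(sprintf("filter_multimapped: removed %d record(s).", n_removed))
  structure(records[keep_row, ], n_removed = n_removed)
}

#' Require a minimum of unique peptides per protein per MS run
#'
#' Within each MS run, proteins (genes) supported by fewer than
#' `min_peptides` distinct stripped peptide sequences are removed — the
#' scope is per run, so a gene may survive in one run and be dropped in
#' another.
#'
#' @param records Single-gene precursor records (apply [filter_multimapped()]
#'   first).
#' @param min_peptides Minimum distinct peptide sequences (default 2).
#' @return Surviving records, with the removal count in `"n_removed"`.
#' @export
filter_min_unique_peptides <- function(records, min_peptides = 2L) {
  assert_records(records, require_single_gene = TRUE)
  min_peptides <- stopifnot_count(min_peptides, "min_peptides")
  if (nrow(records) == 0) {
    return(structure(records, n_removed = 0L))
  }
  gene <- map_chr(records$gene_ids, 1L)
  key <- paste(records$run_id, gene, sep = "\r")
  n_pep <- tapply(records$stripped_peptide, key,
                  function(x) length(unique(x)))
  keep_row <- n_pep[key] >= min_peptides
  n_removed <- sum(!keep_row)
  inform(sprintf("filter_min_unique_peptides: removed %d record(s).", n_removed))
  structure(records[keep_row, ], n_removed = n_removed)
}

#' Keep records whose gene belongs to a reference database
#'
#' Restricts single-gene records to the genes of a sequence database —
#' typically the target database, so that entrapment hits (which feed the
#' FDR estimate, not the quantification) are excluded from abundance maps.
#'
#' @param records Single-gene precursor records.
#' @param db Sequence database tibble whose `gene` column defines the keep
#'   set.
#' @return Surviving records, with the removal count in `"n_removed"`.
#' @export
select_target_genes <- function(records, db) {
  assert_records(records, require_single_gene = TRUE)
  keep_row <- map_chr(records$gene_ids, 1L) %in% db$gene
  n_removed <- sum(!keep_row)
  inform(sprintf("select_target_genes: removed %d record(s).", n_removed))
  structure(records[keep_row, ], n_removed = n_removed)
}

#' Keep records from samples with a given disease status
#'
#' Baseline abundance maps are computed from healthy/normal samples only;
#' this filter keeps the records whose run belongs to a sample with the
#' requested status.
#'
#' @param records Precursor record tibble.
#' @param metadata Run-level metadata from [read_sdrf()] or
#'   [generate_study_design()].
#' @param status Disease status to keep (default `"normal"`).
#' @return Surviving records, with the removal count in `"n_removed"`.
#' @export
select_samples <- function(records, metadata, status = "normal") {
  assert_records(records)
  unknown <- setdiff(unique(records$run_id), metadata$run_id)
  if (length(unknown) > 0) {
    abort(sprintf("Run(s) missing from metadata: %s.",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "diabaq_mapping_error")
  }
  status_of <- setNames(metadata$disease_status, metadata$run_id)
  keep_row <- status_of[records$run_id] == status
  n_removed <- sum(!keep_row)
  inform(sprintf("select_samples: removed %d record(s).", n_removed))
  structure(records[keep_row, ], n_removed = n_removed)
}
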