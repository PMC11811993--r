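test_that("tryptic digestion matches hand-derived cases", {
  expect_identical(digest_tryptic(""), character(0))
  expect_identical(digest_tryptic("AAAAAAAKCCCCCCCR"),
                   c("AAAAAAAK", "CCCCCCCR"))
  # proline suppression: no cut before P
  expect_identical(digest_tryptic("AAAAAAAKPCCCCCCR"), c("AAAAAAAKPCCCCCCR"))
  # length window: a 6-mer fragment is dropped
  expect_identical(digest_tryptic("AAAAAKCCCCCCCR"), "CCCCCCCR")
  # missed cleavages emit concatenations of adjacent fragments
  rules1 <- digestion_rules(missed_cleavages = 1)
  expect_setequal(digest_tryptic("AAAAAAAKCCCCCCCR", rules1),
                  c("AAAAAAAK", "CCCCCCCR", "AAAAAAAKCCCCCCCR"))
})

test_that("digestion agrees with the brute-force enumeration oracle", {
  withr::local_seed(101)
  for (i in 1:60) {
    seq <- random_protein(sample(10:80, 1))
    rules <- digestion_rules(
      min_length = sample(4:7, 1),
      max_length = sample(12:30, 1),
      missed_cleavages = sample(0:2, 1)
    )
    expect_setequal(digest_tryptic(seq, rules), oracle_digest(seq, rules))
  }
})

test_that("theoretical peptide counting flags zero-peptide genes and ignores order", {
  db <- tibble::tibble(
    accession = c("P1", "P2"),
    gene = c("G1", "G2"),
    sequence = c("AAAAAA", "AAAAAAAKCCCCCCCR"), # K/R-free vs two peptides
    organism = "x", is_contaminant = FALSE
  )
  counts <- suppressMessages(count_theoretical_peptides(db))
  expect_equal(counts$n_peptides[counts$gene == "G1"], 0L)
  expect_true(counts$flagged[counts$gene == "G1"])
  expect_equal(counts$n_peptides[counts$gene == "G2"], 2L)

  counts_rev <- suppressMessages(count_theoretical_peptides(db[2:1, ]))
  expect_equal(counts, counts_rev)
})

test_that("run- and sample-level aggregation take medians over evidence", {
  recs <- make_records("r1", "G1", c("PEP1", "PEP2", "PEP3"),
                       quantity = c(1, 2, 3))
  m <- aggregate_run_abundance(recs)
  expect_equal(m$value, 2)

  recs2 <- make_records("r1", "G1", c("PEP1", "PEP2"), quantity = c(1, 3))
  expect_equal(aggregate_run_abundance(recs2)$value, 2) # even: mean of middle two

  # sample collapse ignores missing runs: {2, missing, 4} -> 3
  meta <- tibble::tibble(
    run_id = c("r1", "r2", "r3"), sample_id = "s1", dataset_id = "DS01",
    tissue = "brain", disease_status = "normal"
  )
  recs3 <- dplyr::bind_rows(
    make_records("r1", "G1", c("PEPA", "PEPB"), quantity = 2),
    make_records("r3", "G1", c("PEPA", "PEPB"), quantity = 4),
    make_records("r2", "G2", c("PEPA", "PEPB"), quantity = 7)
  )
  sm <- aggregate_sample_abundance(aggregate_run_abundance(recs3, meta), meta)
  expect_equal(sm$value[sm$gene == "G1"], 3)
  expect_equal(sm$value[sm$gene == "G2"], 7)

  orphan <- aggregate_run_abundance(make_records("rX", "G1", "PEP"))
  expect_error(aggregate_sample_abundance(orphan, meta),
               class = "diabaq_mapping_error")
})

test_that("noiseless simulation is recovered exactly by median aggregation", {
  st <- simulate_study(noiseless_params())
  m <- aggregate_run_abundance(st$report, st$design)
  truth <- st$truth$abundance
  run_sample <- setNames(st$design$sample_id, st$design$run_id)
  expect_equal(m$value,
               truth[cbind(m$gene, unname(run_sample[m$column_id]))])

  # identical noiseless runs collapse to the same per-sample values
  sm <- aggregate_sample_abundance(m, st$design)
  expect_equal(sm$value, truth[cbind(sm$gene, sm$column_id)])
})

test_that("LFQ to iBAQ divides by the theoretical peptide count", {
  counts <- tibble::tibble(gene = c("G1", "G2"), n_peptides = c(2L, 1L),
                           flagged = FALSE)
  m <- matrix_abundance(matrix(c(10, 7), 2, 1,
                               dimnames = list(c("G1", "G2"), "s1")),
                        stage = "lfq")
  ib <- lfq_to_ibaq(m, counts)
  expect_equal(ib$value[ib$gene == "G1"], 5)
  expect_equal(ib$value[ib$gene == "G2"], 7) # count 1: identity
  expect_equal(abundance_stage(ib), "ibaq")

  counts0 <- tibble::tibble(gene = c("G1", "G2"), n_peptides = c(2L, 0L),
                            flagged = c(FALSE, TRUE))
  expect_warning(ib0 <- lfq_to_ibaq(m, counts0), "zero theoretical")
  expect_false("G2" %in% ib0$gene)

  expect_error(lfq_to_ibaq(m, counts[1, ]), class = "diabaq_consistency_error")

  # ranking by iBAQ equals ranking by independently recomputed LFQ/count
  st <- simulate_study(tiny_params(seed = 23))
  recs <- suppressMessages(
    filter_min_unique_peptides(filter_multimapped(
      filter_contaminants(st$report, st$db)))
  )
  recs <- recs[purrr::map_chr(recs$gene_ids, 1) %in% st$db_target$gene, ]
  lfq <- aggregate_run_abundance(recs, st$design)
  cnt <- suppressMessages(count_theoretical_peptides(st$db_target))
  ib2 <- lfq_to_ibaq(lfq, cnt)
  count_of <- setNames(cnt$n_peptides, cnt$gene)
  joined <- dplyr::inner_join(tibble::as_tibble(lfq), tibble::as_tibble(ib2),
                              by = c("gene", "column_id"),
                              suffix = c("_lfq", "_ibaq"))
  for (col in unique(joined$column_id)[1:5]) {
    sub <- joined[joined$column_id == col, ]
    expect_equal(order(sub$value_ibaq),
                 order(sub$value_lfq / count_of[sub$gene]))
  }
})

test_that("rank binning produces near-equal ordered bins", {
  m <- matrix_abundance(matrix(1:10, 10, 1,
                               dimnames = list(paste0("G", 1:10), "s1")))
  b <- bin_abundances(m, 5)
  expect_equal(b$value[order(match(b$gene, paste0("G", 1:10)))],
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_equal(abundance_stage(b), "binned")

  # degenerate ties still give a valid equal-size partition
  ties <- matrix_abundance(matrix(rep(1, 10), 10, 1,
                                  dimnames = list(paste0("G", 1:10), "s1")))
  bt <- bin_abundances(ties, 5)
  expect_equal(sort(unname(table(bt$value))), rep(2L, 5), ignore_attr = TRUE)

  short <- matrix_abundance(matrix(1:3, 3, 1,
                                   dimnames = list(paste0("G", 1:3), "s1")))
  expect_error(bin_abundances(short, 5), class = "diabaq_column_error")
})

test_that("binning matches the sort-and-slice oracle and its invariances", {
  withr::local_seed(202)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    k <- sample(2:8, 1)
    vals <- round(rlnorm(n, 10, 2), 3) # rounding creates ties
    m <- matrix_abundance(matrix(vals, n, 1,
                                 dimnames = list(paste0("G", 1:n), "s1")))
    got <- bin_abundances(m, k)$value
    expect_equal(got, oracle_bins(vals, k))

    # scale invariance
    m2 <- matrix_abundance(matrix(vals * runif(1, 0.1, 100), n, 1,
                                  dimnames = list(paste0("G", 1:n), "s1")))
    expect_equal(bin_abundances(m2, k)$value, got)

    # monotonicity and near-equal sizes
    expect_true(all(diff(got[order(vals)]) >= 0))
    expect_lte(diff(range(table(got))), 1)
  }
})

test_that("per-sample iBAQ recovers ground-truth abundance ranks", {
  # noiseless study: exact rank agreement within equal-peptide-count classes
  st0 <- simulate_study(noiseless_params())
  recs0 <- suppressMessages(
    filter_min_unique_peptides(filter_multimapped(
      filter_contaminants(st0$report, st0$db)))
  )
  cnt0 <- suppressMessages(count_theoretical_peptides(st0$db_target))
  ib0 <- lfq_to_ibaq(
    aggregate_sample_abundance(aggregate_run_abundance(recs0, st0$design),
                               st0$design),
    cnt0
  )
  m0 <- abundance_matrix(ib0)
  truth0 <- st0$truth$abundance[rownames(m0), colnames(m0)]
  count_of <- setNames(cnt0$n_peptides, cnt0$gene)
  for (s in colnames(m0)) {
    for (k in unique(count_of[rownames(m0)])) {
      sel <- which(count_of[rownames(m0)] == k & !is.na(m0[, s]))
      if (length(sel) >= 2) {
        expect_equal(rank(m0[sel, s]), rank(truth0[sel, s]),
                     ignore_attr = TRUE)
      }
    }
  }

  # default-noise study: Spearman >= 0.9 per sample
  st <- simulate_study(tiny_params(seed = 29))
  recs <- suppressMessages(
    filter_min_unique_peptides(filter_multimapped(
      filter_contaminants(st$report, st$db)))
  )
  recs <- recs[purrr::map_chr(recs$gene_ids, 1) %in% st$db_target$gene, ]
  cnt <- suppressMessages(count_theoretical_peptides(st$db_target))
  ib <- lfq_to_ibaq(
    aggregate_sample_abundance(aggregate_run_abundance(recs, st$design),
                               st$design),
    cnt
  )
  m <- abundance_matrix(ib)
  truth <- st$truth$abundance[rownames(m), colnames(m)]
  for (s in colnames(m)) {
    ok <- !is.na(m[, s]) & !is.na(truth[, s])
    rho <- cor(m[ok, s], truth[ok, s], method = "spearman")
    expect_gte(rho, 0.9)
  }
})
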