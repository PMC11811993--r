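sample_cd <- function(ids, tissue, dataset = "DS01") {
  tibble::tibble(column_id = ids, dataset_id = dataset, tissue = tissue,
                 disease_status = "normal")
}

test_that("the fraction of missingness follows NA / (n x g) per tissue block", {
  m <- matrix(1, 3, 2, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
  cd <- sample_cd(c("s1", "s2"), "brain")
  full <- matrix_abundance(m, col_data = cd)
  expect_equal(missingness_fm(full)$fm, 0)

  m2 <- m
  m2[1, 1] <- NA
  m2[2, 2] <- NA
  part <- matrix_abundance(m2, col_data = cd)
  res <- missingness_fm(part)
  expect_equal(res$fm, 2 / 6)
  expect_equal(res$g_genes, 3L)
  expect_equal(res$na_count, 2L)

  # dataset summary is the median over its tissue blocks; G3 never appears
  # in the liver block, so its g counts two genes (4 cells, 1 missing)
  m3 <- cbind(m2, s3 = c(1, NA, NA), s4 = c(1, 1, NA))
  cd3 <- dplyr::bind_rows(sample_cd(c("s1", "s2"), "brain"),
                          sample_cd(c("s3", "s4"), "liver"))
  res3 <- missingness_fm(matrix_abundance(m3, col_data = cd3))
  expect_equal(sort(res3$fm), sort(c(2 / 6, 1 / 4)))
  expect_equal(unique(res3$fm_dataset), median(c(2 / 6, 1 / 4)))

  # a simulated study recovers the configured dropout level
  p <- tiny_params(runs_per_sample = 1, dropout_max = 0.4,
                   dropout_slope = 0.8, dropout_quantile = 0.5, seed = 53)
  st <- simulate_study(p)
  recs <- suppressMessages(filter_multimapped(
    filter_contaminants(st$report, st$db)))
  recs <- recs[purrr::map_chr(recs$gene_ids, 1) %in% st$db_target$gene, ]
  sm <- aggregate_sample_abundance(
    aggregate_run_abundance(recs, st$design), st$design)
  fm <- missingness_fm(sm)
  # expected missingness per tissue block from the dropout model itself
  ab <- st$truth$abundance
  mid <- log(quantile(ab, p$dropout_quantile, na.rm = TRUE, names = FALSE))
  pm <- p$dropout_max * plogis(-p$dropout_slope * (log(ab) - mid))
  cd_st <- dplyr::distinct(st$design, column_id = sample_id, dataset_id, tissue)
  for (i in seq_len(nrow(fm))) {
    cols <- cd_st$column_id[cd_st$dataset_id == fm$dataset_id[i] &
                              cd_st$tissue == fm$tissue[i]]
    probs <- pm[, cols, drop = FALSE]
    probs <- probs[rowSums(is.na(probs)) == 0, , drop = FALSE]
    n <- ncol(probs)
    # genes missing in every sample drop out of g, so condition on >=1 hit
    q_all <- apply(probs, 1, prod)
    mu_na <- sum(rowSums(probs)) - n * sum(q_all)
    mu_g <- sum(1 - q_all)
    mu_fm <- mu_na / (n * mu_g)
    se <- sqrt(sum(probs * (1 - probs))) / (n * mu_g)
    expect_lt(abs(fm$fm[i] - mu_fm), 3 * se)
  }
})

test_that("pairwise binned correlations match independent recomputation", {
  withr::local_seed(61)
  n <- 40
  m <- matrix(sample(1:5, n * 6, replace = TRUE), n, 6,
              dimnames = list(paste0("G", 1:n), paste0("s", 1:6)))
  m[sample(length(m), 40)] <- NA
  cd <- sample_cd(paste0("s", 1:6), rep(c("brain", "liver"), each = 3))
  corr <- pairwise_binned_correlation(
    matrix_abundance(m, stage = "binned", col_data = cd))

  # every cell equals the brute-force oracle on the common-gene sub-vectors
  for (i in seq_len(nrow(corr))) {
    expect_equal(corr$r2[i], oracle_r2(m[, corr$sample_a[i]],
                                       m[, corr$sample_b[i]]))
  }

  # symmetry and unit diagonal
  cm <- correlation_matrix(corr)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 6))

  # a sample against itself and perfect anticorrelation
  m2 <- cbind(a = 1:5, b = 5:1)
  rownames(m2) <- paste0("G", 1:5)
  corr2 <- pairwise_binned_correlation(
    matrix_abundance(m2, stage = "binned",
                     col_data = sample_cd(c("a", "b"), "brain")))
  ab <- corr2[corr2$sample_a == "a" & corr2$sample_b == "b", ]
  expect_equal(ab$r2, 1)
  expect_equal(ab$r, -1) # sign retained alongside r^2
  expect_equal(corr2$r2[corr2$sample_a == "a" & corr2$sample_b == "a"], 1)

  # binned input is required
  expect_error(pairwise_binned_correlation(
    matrix_abundance(m2, stage = "ibaq")), class = "diabaq_invalid_input")
})

test_that("median group correlations summarise within-group sample pairs", {
  m <- cbind(a = c(1:5, NA), b = c(1:5, NA), c = c(5:1, NA), single = 1:6)
  rownames(m) <- paste0("G", 1:6)
  cd <- sample_cd(c("a", "b", "c", "single"),
                  c("brain", "brain", "brain", "liver"))
  corr <- pairwise_binned_correlation(
    matrix_abundance(m, stage = "binned", col_data = cd))
  med <- median_group_correlation(corr, "tissue")
  expect_equal(med$median_r2[med$group == "brain"], 1) # all |r| = 1 pairs
  expect_true(is.na(med$median_r2[med$group == "liver"])) # single sample

  # within-tissue exceeds between-tissue on simulated data
  st <- simulate_study(tiny_params(seed = 59))
  recs <- suppressMessages(
    filter_min_unique_peptides(filter_multimapped(
      filter_contaminants(st$report, st$db))))
  recs <- recs[purrr::map_chr(recs$gene_ids, 1) %in% st$db_target$gene, ]
  cnt <- suppressMessages(count_theoretical_peptides(st$db_target))
  binned <- bin_abundances(lfq_to_ibaq(
    aggregate_sample_abundance(aggregate_run_abundance(recs, st$design),
                               st$design), cnt))
  corr_st <- pairwise_binned_correlation(binned)
  within <- median_group_correlation(corr_st, "tissue")
  cd_st <- attr(corr_st, "col_data")
  tissue_of <- setNames(cd_st$tissue, cd_st$column_id)
  between_cells <- corr_st[tissue_of[corr_st$sample_a] !=
                             tissue_of[corr_st$sample_b], ]
  expect_gt(min(within$median_r2), median(between_cells$r2, na.rm = TRUE))
})

test_that("cross-study comparison joins genes per tissue and tracks noise", {
  a <- tidyr::expand_grid(gene = paste0("G", 1:50),
                          tissue = c("brain", "liver"))
  withr::local_seed(67)
  a$abundance <- rlnorm(nrow(a), 10, 1.5)

  self <- cross_study_compare(a, a)
  expect_equal(self$r2, rep(1, 2))
  expect_equal(self$n_genes, rep(50L, 2))

  doubled <- dplyr::mutate(a, abundance = abundance * 2)
  expect_equal(cross_study_compare(a, doubled)$r2, rep(1, 2))

  # r^2 decreases as independent noise grows
  r2_at <- vapply(c(0.3, 1, 3), function(sd) {
    b <- dplyr::mutate(a, abundance = abundance *
                         withr::with_seed(71, rlnorm(nrow(a), 0, sd)))
    mean(cross_study_compare(a, b)$r2)
  }, numeric(1))
  expect_true(all(diff(r2_at) < 0))

  empty <- cross_study_compare(a, dplyr::mutate(a, gene = paste0("X", gene)))
  expect_true(all(is.na(empty$r2)))
  expect_error(cross_study_compare(a[, 1:2], a),
               class = "diabaq_invalid_input")
})

test_that("gene-set overlap summaries report counts and anchored percentages", {
  withr::local_seed(73)
  universe <- sprintf("ENSG%08d", 1:14000)
  common <- sample(universe, 8449)
  a_only <- sample(setdiff(universe, common), 13071 - 8449)
  b_only <- sample(setdiff(universe, c(common, a_only)), 9299 - 8449)
  ov <- overlap_summary(c(common, a_only), c(common, b_only))
  expect_equal(ov$n_a, 13071L)
  expect_equal(ov$n_b, 9299L)
  expect_equal(ov$n_common, 8449L)
  expect_equal(ov$pct_common, 64.6)
  expect_equal(ov$pct_b_only, 9.1)
  expect_equal(ov$pct_a_only, 35.4)

  # conservation
  expect_equal(ov$n_common + ov$n_a_only, ov$n_a)
  expect_equal(ov$n_common + ov$n_b_only, ov$n_b)

  same <- overlap_summary(c("A", "B"), c("B", "A"))
  expect_equal(same$pct_common, 100)
  disjoint <- overlap_summary(c("A", "B"), c("C"))
  expect_equal(disjoint$n_common, 0L)
})

test_that("coverage summarises per-tissue identification and tissue sharing", {
  m <- matrix(c(1, 1, NA,
                1, NA, NA,
                1, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), c("s1", "s2", "s3")))
  cd <- sample_cd(c("s1", "s2", "s3"), c("brain", "liver", "liver"))
  cov <- coverage_summary(matrix_abundance(m, col_data = cd))
  expect_equal(cov$total_genes, 3L)
  expect_equal(cov$by_tissue$n_genes[cov$by_tissue$tissue == "brain"], 3L)
  expect_equal(cov$by_tissue$pct_of_total[cov$by_tissue$tissue == "brain"], 100)
  expect_equal(cov$n_all_tissues, 2L) # G1 and G3 in both tissues
  expect_equal(cov$n_single_tissue, 1L) # G2 in brain only

  # a single-tissue study makes every gene single-tissue
  cov1 <- coverage_summary(matrix_abundance(
    m, col_data = sample_cd(c("s1", "s2", "s3"), "brain")))
  expect_equal(cov1$n_single_tissue, cov1$total_genes)
  expect_equal(cov1$n_all_tissues, cov1$total_genes)

  # without dropout, the all-tissue count equals the configured core fraction
  st <- simulate_study(noiseless_params())
  recs <- suppressMessages(filter_multimapped(
    filter_contaminants(st$report, st$db)))
  sm <- aggregate_sample_abundance(
    aggregate_run_abundance(recs, st$design), st$design)
  cov_st <- coverage_summary(sm)
  n_core <- length(st$truth$core_genes)
  expect_equal(cov_st$n_all_tissues, n_core)
})
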