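---
title: "From DIA precursor reports to comparable tissue abundance maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DIA precursor reports to comparable tissue abundance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabaq)
library(dplyr)
```

## The problem

Label-free DIA proteomics experiments quantify tens of thousands of
precursors per MS run, reported by search engines such as DIA-NN as one tall
table per study: run, protein group, gene group, stripped peptide sequence,
precursor quantity, q-value. Comparing protein abundances *across* samples,
tissues and independently acquired datasets from such tables requires a
disciplined post-processing chain, because raw LFQ intensities are neither
comparable across proteins (ionization efficiency and peptide count differ)
nor across experiments (batch effects can exceed biology). diabaq implements
that chain as composable, pipe-friendly functions operating on tibbles.

## Peptide-evidence filtering

Three filters run in a fixed order:

1. **Contaminants** — any record whose protein group contains a contaminant
   accession (a cRAP-style set) is removed. The test is deliberately
   conservative: evidence shared with a contaminant is ambiguous and
   discarded whole.
2. **Multi-mapping** — records whose protein or gene group lists more than
   one identifier are removed, so each surviving record ties one peptide
   observation to one canonical protein (we use gene identifiers as
   canonical protein labels throughout).
3. **Minimum unique peptides** — within each MS run, proteins supported by
   fewer than two distinct stripped peptide sequences are dropped. The
   scope is per run: a protein may survive in one run and fail in another.

The order matters only in that the peptide-count filter must see single-gene
records; contaminant and multi-map filters commute (this is tested). Each
filter is idempotent and reports its removal count, so
`input = survivors + removed` holds per stage and the pipeline manifest is
auditable. A q-value cutoff (default 0.01) is applied at ingest, standing in
for the run-level threshold a search engine would have applied.

## Quantification: medians, iBAQ, quintile bins

Within each run, a protein's LFQ abundance is the **median** of its
precursor quantities; runs collapse to samples again by the median,
ignoring missing cells. Medians are used for every aggregation step in the
package — they are robust to the heavy right tail of intensity data and
keep all collapse rules consistent.

LFQ intensities scale with how many peptides a protein can contribute. The
**iBAQ** transform divides each LFQ value by the protein's count of
theoretical tryptic peptides, computed by in-silico digestion of the
canonical sequence. The digestion defaults describe trypsin as modelled by
mainstream search engines: cleave after K or R, suppressed before P, no
missed cleavages, peptides of 7–30 residues counted as observable. These
rules are a modelling choice, not a universal constant, so
`digestion_rules()` exposes every one of them; the implementation is checked
against a brute-force substring enumerator in the test suite. Proteins whose
sequence yields no observable peptide cannot receive iBAQ values and are
dropped with a warning.

For cross-dataset comparison, iBAQ values are converted to **ranked bins**:
within each sample, present values are sorted ascending and split into five
groups whose sizes differ by at most one; bin 1 is lowest abundance, bin 5
highest. Binning is per sample (per column) because the comparisons the
bins feed — sample-to-sample correlation heatmaps, cross-study tissue
comparisons — are exactly the ones where between-sample scale and batch
effects would otherwise dominate. Ties are broken by stable input order, so
the assignment is deterministic; bins are invariant to positive rescaling
of a column (tested as a property).

## Entrapment FDR across datasets

Each dataset is searched and thresholded individually; collating proteins
over many datasets can inflate the effective protein FDR well beyond the
per-dataset level. To estimate the combined FDR, an entrapment database
(a foreign proteome, e.g. *Arabidopsis thaliana* against human targets) is
appended to the search space. Protein groups whose gene identifiers are
*exclusively* entrapment are decoys; every other group — including mixed
groups — is a target. With group presence counted as "observed with at
least two peptides in at least one run of the dataset", the estimate for
proteins observed in at least `k` datasets is

$$\mathrm{FDR}(k) = D_n \cdot \frac{\#\{\text{decoys present in} \ge k\}}
{\#\{\text{targets present in} \ge k\}},
\qquad D_n = \frac{|\text{target db}|}{|\text{entrapment db}|}.$$

The cumulative ("at least k") form makes both counts non-increasing in `k`,
and the table is tested for exact agreement with cumulative sums of the
presence histogram. $D_n$ rescales the decoy count for the size imbalance
between the two databases; `pipeline_config(dn_mode=)` offers the exact
ratio (default) or the ratio rounded to one decimal, since published
analyses sometimes quote the rounded value. Group identity across datasets
is the sorted gene-id tuple. Entrapment estimators can exceed 1 on small
inputs, so the raw value is reported alongside a `[0, 1]`-clamped copy.

## Missingness, coverage and correlation

The **fraction of missingness** of a tissue within a dataset is
$F_m = \mathrm{NA} / (n \cdot g)$, where $n$ is the tissue's sample count,
$g$ the number of genes identified in at least one of those samples, and
NA the missing cells of that $g \times n$ block. Defining $g$ within the
tissue block (rather than against the dataset- or study-wide gene universe)
keeps $F_m$ a property of the block itself; the study-wide alternative
would conflate tissue coverage differences with within-tissue dropout.
Datasets spanning several tissues are summarised by the median of their
tissue $F_m$ values.

Sample-to-sample comparisons use **squared Pearson correlations of binned
values restricted to commonly identified proteins** (present in both
samples). Cells with fewer than 3 common genes or zero variance in either
restricted vector are flagged undefined rather than propagated. $R^2$
discards the sign, which is informative for diagnostics, so the signed `r`
travels alongside. Group summaries take the median over defined
off-diagonal within-group cells; both tissue-level and
tissue-within-dataset groupings are available because multi-dataset tissues
can be summarised either way. Cross-study comparisons inner-join two
gene-keyed tables per tissue, optionally log2-transform, and report $R^2$
with the joined gene count; set overlaps are reported as exact set
arithmetic with percentages anchored on each study's own total (rounded to
one decimal only at presentation — published one-decimal figures derived
from pre-rounded intermediates may differ in the last digit, and the
package deliberately does not reproduce such rounding artifacts).

## The synthetic study generator

Real multi-dataset DIA studies cannot be re-downloaded and re-searched at
desk scale, so the generator emits the same artifact set the pipeline
consumes — report TSVs, target/entrapment/contaminant FASTA, SDRF-like
metadata — from a known ground truth:

* **Sequences** are concatenations of tryptic peptides (bodies free of K/R,
  no leading P, terminal K/R), so the default digestion recovers exactly
  the built-in peptides and peptide counts are known.
* **Abundances**: per-gene base log-abundance drawn once
  (`abundance_sdlog = 2.3` natural-log units, about one log10 unit of
  between-gene spread — a deliberately compressed but realistic slice of
  the several-orders-of-magnitude dynamic range of real proteomes), plus a
  per-tissue effect (`tissue_effect_sd = 1.0`) that makes within-tissue
  sample pairs more similar than cross-tissue pairs. A configurable core
  fraction (default 0.6) of genes is expressed in every tissue; the rest
  are restricted to random tissue subsets.
* **Report rows**: quantity = abundance × fixed peptide-specific response
  factor (log-normal, sd 0.4) × per-row noise; multiplicative log-normal
  noise is the standard first-order model for LFQ intensities.
* **Dropout** is logistic in log abundance — low-abundance proteins go
  missing more often, which is the feature that missingness and coverage
  statistics are sensitive to. `dropout_max = 0` turns it off for exact
  recovery tests.
* **Artifacts**: contaminant rows, entrapment-only decoy groups at a
  configurable fraction of emitted groups, and two-gene protein groups,
  each with per-run counts recorded in an injection log so filter tests can
  assert exact removal counts.

The generator emulates the *tabular* structure and first-order statistics
of DIA-NN output. It does not simulate spectra, retention times,
interference, shared peptides between target genes, or correlated batch
effects; passing tests therefore demonstrate correctness of the
post-processing arithmetic under the stated statistical model, not
robustness to every pathology of real data. The 15-dataset, 12-tissue,
356-run/178-sample design of a published human tissue survey is available
exactly at the metadata level via `tissue_atlas_design()`.

Default test problem sizes — a few hundred genes, 2–3 datasets, 2–4
tissues, 24–96 runs — were chosen once as the smallest sizes at which the
statistical assertions (3-standard-error recovery bands, Spearman ≥ 0.9
rank recovery) have comfortable margins.

## Numerical choices and degenerate inputs

* Binning: bin sizes are `floor(n/k)` or `ceiling(n/k)` via the rank rule
  `ceiling(rank * k / n)`; ties keep input order (R's stable `order()`).
  Columns with fewer present values than bins are an error, not a silent
  degenerate binning.
* Medians of even counts are the mean of the middle two (R's default).
* Zero-peptide genes are excluded from iBAQ, with a logged warning.
* Undefined statistics (empty joins, constant vectors, single-sample
  groups, zero identified genes) are `NA` with a flag or warning — never
  silently dropped or zero-filled.
* Report writers serialise numeric columns with 17 significant digits so a
  write/read round trip is exact and fixed-seed runs are byte-identical.

## A worked run

```{r example, eval = FALSE}
params <- sim_params(n_datasets = 2, tissues = c("brain", "liver"), seed = 1)
study <- simulate_study(params)

records <- study$report |>
  filter_contaminants(study$db) |>
  filter_multimapped() |>
  filter_min_unique_peptides() |>
  select_samples(study$design) |>
  select_target_genes(study$db_target)

counts <- count_theoretical_peptides(study$db_target)
ibaq <- aggregate_run_abundance(records, study$design) |>
  aggregate_sample_abundance(study$design) |>
  lfq_to_ibaq(counts)
binned <- bin_abundances(ibaq)

presence <- classify_protein_groups(
  filter_contaminants(study$report, study$db),
  study$db_entrapment$gene
)
fdr <- fdr_at_k(presence, compute_dn(nrow(study$db_target),
                                     nrow(study$db_entrapment)))
glance(fdr)

missingness_fm(ibaq)
median_group_correlation(pairwise_binned_correlation(binned), "tissue")
```

The same chain, driven by files on disk, is available as
`run_pipeline(pipeline_config(...))`, which also writes the abundance
matrices, FDR table, histogram and a JSON manifest with per-stage counts
and content hashes.

## Known limitations

* Abundances are keyed by gene ("canonical protein"); isoform-level
  quantification is out of scope.
* The FDR estimator is a protein-group-level entrapment estimate across
  datasets; it is not a peptide- or precursor-level FDR and does not model
  the search engine's internal corrections.
* Tissue-specificity calling is out of scope: with heterogeneous per-tissue
  coverage, absence of evidence in a tissue is not evidence of absence.
* The generator's independence assumptions (independent dropout and noise
  across genes and runs) understate the correlation structure of real
  batch effects.
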