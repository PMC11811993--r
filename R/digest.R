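#' Tryptic digestion rules
#'
#' Parameters of the in-silico protease used to enumerate theoretical
#' peptides. The defaults describe trypsin as modelled by mainstream DIA
#' search engines: cleavage C-terminal of lysine (K) or arginine (R), no
#' cleavage when the following residue is proline (P), no missed cleavages,
#' and peptides of 7 to 30 residues counted as observable.
#'
#' @param cleave_after Residues after which the backbone is cut.
#' @param suppress_before Residues that block a cut when they follow the
#'   cleavage site.
#' @param min_length,max_length Inclusive length bounds (residues) for a
#'   peptide to count as theoretically observable.
#' @param missed_cleavages Maximum number of internal cleavage sites a
#'   reported peptide may retain.
#'
#' @return An object of class `digestion_rules`.
#' @export
#' @examples
#' digestion_rules()
digestion_rules <- function(cleave_after = c("K", "R"),
                            suppress_before = "P",
                            min_length = 7L,
                            max_length = 30L,
                            missed_cleavages = 0L) {
  min_length <- stopifnot_count(min_length, "min_length", min = 1L)
  max_length <- stopifnot_count(max_length, "max_length", min = min_length)
  missed_cleavages <- stopifnot_count(missed_cleavages, "missed_cleavages", min = 0L)
  structure(
    list(cleave_after = toupper(cleave_after),
         suppress_before = toupper(suppress_before),
         min_length = min_length,
         max_length = max_length,
         missed_cleavages = missed_cleavages),
    class = "digestion_rules"
  )
}

#' In-silico tryptic digestion of one protein sequence
#'
#' Cuts the sequence after every residue in `rules$cleave_after` unless the
#' next residue is in `rules$suppress_before`; with `missed_cleavages = m`,
#' concatenations of up to `m + 1` adjacent fragments are also emitted.
#' Distinct peptides within the configured length window are returned.
#'
#' @param sequence A single amino-acid string. An empty string yields an
#'   empty peptide set.
#' @param rules A [digestion_rules()] object.
#'
#' @return Character vector of distinct peptides (order of first occurrence).
#' @export
#' @examples
#' digest_tryptic("AAAAAAAKCCCCCCCR")
digest_tryptic <- function(sequence, rules = digestion_rules()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) return(character(0))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # cut after i when res[i] is a cleavage residue and res[i+1] does not block
  cut_after <- res %in% rules$cleave_after &
    c(!res[-1] %in% rules$suppress_before, FALSE)
  cut_after[n] <- TRUE
  ends <- which(cut_after)
  starts <- c(1L, head(ends, -1L) + 1L)
  m <- rules$missed_cleavages
  peptides <- character(0)
  for (i in seq_along(starts)) {
    for (j in i:min(i + m, length(ends))) {
      len <- ends[j] - starts[i] + 1L
      if (len >= rules$min_length && len <= rules$max_length) {
        peptides <- c(peptides, substr(sequence, starts[i], ends[j]))
      }
    }
  }
  unique(peptides)
}

#' Theoretical tryptic peptide counts per gene
#'
#' The per-gene count of distinct in-range tryptic peptides is the
#' denominator of the LFQ-to-iBAQ conversion. Genes whose canonical sequence
#' yields no observable peptide are flagged: they cannot receive iBAQ values.
#'
#' @param db A protein sequence database tibble, as returned by
#'   [read_fasta()] or [generate_sequence_db()].
#' @param rules A [digestion_rules()] object.
#'
#' @return A tibble with columns `gene`, `n_peptides`, `flagged`
#'   (`TRUE` when `n_peptides == 0`).
#' @export
count_theoretical_peptides <- function(db, rules = digestion_rules()) {
  if (nrow(db) == 0) {
    abort("Sequence database is empty.", class = "diabaq_invalid_input")
  }
  counts <- vapply(db$sequence, function(s) length(digest_tryptic(s, rules)),
                   integer(1), USE.NAMES = FALSE)
  out <- tibble(gene = db$gene, n_peptides = counts) |>
    group_by(.data$gene) |>
    summarise(n_peptides = as.integer(sum(.data$n_peptides)), .groups = "drop") |>
    mutate(flagged = .data$n_peptides == 0L) |>
    arrange(.data$gene)
  if (any(out$flagged)) {
    inform(sprintf("%d gene(s) yield no theoretical tryptic peptide and are flagged.",
                   sum(out$flagged)))
  }
  out
}
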