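# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# Enumerate every substring and keep those that start at the sequence start
# or right after a valid cleavage site, end at a valid site or the sequence
# end, contain at most `missed` internal cleavage sites, and fall in the
# length window. O(L^2).
oracle_digest <- function(sequence, rules = digestion_rules()) {
  n <- nchar(sequence)
  if (n == 0L) return(character(0))
  res <- strsplit(toupper(sequence), "")[[1]]
  is_cut <- function(i) {
    # TRUE when the backbone is cut after residue i
    if (i < 1 || i >= n) return(i == n)
    res[i] %in% rules$cleave_after && !(res[i + 1] %in% rules$suppress_before)
  }
  peps <- character(0)
  for (s in 1:n) {
    if (!(s == 1 || is_cut(s - 1))) next
    for (e in s:n) {
      if (!(e == n || is_cut(e))) next
      internal <- if (e > s) sum(vapply(s:(e - 1), is_cut, logical(1))) else 0L
      if (internal > rules$missed_cleavages) next
      len <- e - s + 1L
      if (len >= rules$min_length && len <= rules$max_length) {
        peps <- c(peps, paste(res[s:e], collapse = ""))
      }
    }
  }
  unique(peps)
}

# Sort ascending (stable), slice into n_bins nearly equal chunks whose
# cumulative boundaries are floor(j * n / n_bins), map back to input order.
oracle_bins <- function(values, n_bins) {
  n <- length(values)
  boundaries <- floor(seq_len(n_bins) * n / n_bins)
  sizes <- diff(c(0L, boundaries))
  ord <- order(values)
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), sizes)
  bins
}

# Materialize the common-gene sub-vectors of two matrix columns and
# recompute the squared Pearson correlation from first principles.
oracle_r2 <- function(a, b) {
  common <- which(!is.na(a) & !is.na(b))
  if (length(common) < 3) return(NA_real_)
  x <- a[common]
  y <- b[common]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE),
        collapse = "")
}
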