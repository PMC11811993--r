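Package: diabaq
Title: Post-Processing of DIA Proteomics Reports into iBAQ Tissue Abundance Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Turns precursor-level reports from data-independent acquisition
    (DIA) proteomics searches into comparable per-sample protein abundance
    tables. Implements peptide-evidence filtering (contaminant removal,
    multi-mapping removal, a minimum of two unique peptides per protein per MS
    run), median aggregation of precursor quantities, conversion of label-free
    quantification (LFQ) intensities to intensity-based absolute quantification
    (iBAQ) via theoretical tryptic peptide counts, ranked quintile binning,
    entrapment-database false discovery rate estimation across datasets,
    missing-value quantification, and binned-abundance correlation analyses
    within and across studies. Ships a synthetic DIA study generator so the
    whole pipeline is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
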