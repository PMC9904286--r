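Package: pepprofile
Title: Per-Residue Peptide Intensity Profiles for Bottom-Up Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Converts peptide-level database-search result tables and a FASTA
    protein database into quantitative per-residue intensity profiles of a
    chosen protein. Supports PEAKS, MSFragger/FragPipe, MaxQuant,
    MetaMorpheus and Proteome Discoverer export dialects plus a generic CSV,
    regex-based grouping of replicates, sequence coverage and peptide
    uniqueness classification, multi-sample comparison (overlay, difference,
    fold change with explicit infinity handling), peptide-level volcano
    statistics, sequence-motif and PTM annotation, stacked-peptide layouts,
    and CSV/PNG export. A seeded synthetic-data generator produces
    dialect-faithful toy inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
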