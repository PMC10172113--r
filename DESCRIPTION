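Package: priomics
Title: Prioritized Single-Cell Proteomics Acquisition and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for prioritized data-dependent acquisition in
    single-cell proteomics. Simulates LC-MS duty cycles under topN shotgun or
    multi-tier priority scheduling with real-time retention-time alignment,
    builds tiered inclusion lists from peptide-spectrum-match tables with
    decoy-based FDR control and intensity-dependent fill times, augments
    protein FASTA databases with semi-tryptic protease cleavage products,
    filters and normalizes isobaric reporter-ion single-cell matrices, and
    provides the associated statistics: intensity-binned null-model
    differential abundance, protein-set enrichment on principal-component
    loadings, permutation-based marker association, and spike-in accuracy
    regression. All inputs can be emulated by the bundled synthetic-fixture
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
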