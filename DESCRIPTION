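Package: gapsmith
Title: Assembly-to-Assembly Gap Closing and Reference Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating a chromosome-level reference assembly against
    donor assemblies of the same genome. Detects and classifies polyN assembly
    gaps, uses gap-flanking genes as synteny anchors to extract gap-closing
    sequences (GCSs) from donor assemblies, validates candidate sequences by
    flank alignment and read-depth comparison, applies the selected edits
    while maintaining an old-to-new coordinate liftover, recovers missing
    distal telomeres from donors via terminal gene anchors and telomeric
    repeat (TTAGG/CCTAA) density scans, places unlocalized scaffolds by
    gene-order consensus across donors, removes scaffolds made redundant by
    the edits, and emits a corrected assembly with lifted annotations and a
    complete edit ledger. Includes a seeded synthetic truth-set generator so
    the whole workflow is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
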