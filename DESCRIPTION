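Package: sigbar
Title: Patient-Specific Signaling Barcodes from Surprisal Analysis of
    Proteomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes tumor proteomic matrices (e.g. reverse phase protein
    array panels) into a balanced steady state plus a small number of
    unbalanced processes using surprisal analysis fitted by singular value
    decomposition of the ln-expression matrix.  Assigns each sample a
    -1/0/1 barcode of significantly active processes, catalogs barcode
    recurrence and rarity across a cohort, assembles per-process signed
    protein subnetworks from a protein-protein interaction edge list,
    ranks druggable hub proteins, and designs per-sample drug combinations
    that cover every active process by greedy weighted set cover.  Includes
    a synthetic-data generator with planted processes so that every stage
    of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
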