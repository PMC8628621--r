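Package: phylotable
Title: Coupled Phylogenetic Trees and Trait Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Couples one or more phylogenetic trees to a taxon-by-character
    trait table through a single name-matching step and then keeps the two
    mutually consistent across every subsequent operation.  Rows filtered,
    grouped or derived with 'data.table' syntax prune the matching tips from
    every tree; taxa dropped from the trees remove the matching rows; grouped
    aggregations that destroy the row-to-taxon bijection detach the table with
    a warning.  Includes a literal-label Newick reader/writer, tip pruning
    that conserves root-to-tip path lengths, discrete/continuous character
    detection and filtering, named-vector extraction for downstream
    comparative methods, a synthetic benchmark-data generator, a timing
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    data.table,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
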