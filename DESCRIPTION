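Package: ubigain
Title: Detection, Dating and Classification of Ubiquitylation-Site Gains
    in the Human Lineage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps experimentally observed lysine ubiquitylation sites onto
    orthologous mammalian protein alignments, screens for lineage-specific
    lysine gains in conserved regions, dates each gain to the smallest
    enclosing clade on the human-lineage clade ladder, and classifies each
    gained site as a new, additional, or shifted ubiquitylation target via
    a window analysis around the modified residue. Includes a species-tree
    aware sequence simulator with planted lysine gains and confounder
    patterns so the whole pipeline can be validated against known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
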