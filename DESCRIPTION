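Package: svconcord
Title: Concordance of Structural Rearrangements Between Paired Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chromosomal rearrangements of clonally related tumor
    pairs (for example a primary tumor and its distant metastasis) as shared or
    sample-specific by windowed breakpoint matching with sub-threshold "rescue"
    and read-pair "look-up" steps, and derives the downstream concordance
    analyses: directional and combined similarity percentages, copy-number
    profile similarity over union-break windows, presence/absence rearrangement
    barcodes with hierarchical clustering, coverage-normalized clonality tables,
    rearrangement hotspot detection by kernel density, and permutation-based
    genic and cancer-gene enrichment tests. Includes a synthetic cohort
    generator so the full pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
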