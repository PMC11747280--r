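Package: breakscape
Title: Integrative Analysis of Chromatin Architecture Around DNA Double-Strand Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and simulation tools for studying how chromatin
    architecture shapes DNA double-strand-break (DSB) repair. Implements
    ChIP-seq enrichment statistics around induced breaks (distance-shell and
    inside/outside-domain fold changes with pseudocounts), observed/expected
    normalization of Hi-C contact matrices with intra- and inter-domain
    interaction scores, 4C-like viewpoint tracks and trans translocation-window
    sums, and downstream analytics for high-throughput genome-wide
    translocation sequencing (HTGTS) junction libraries (bait filtering,
    cis/trans classification, damage-context assignment, microhomology
    profiling). A seeded synthetic-data generator emulates a TAD-partitioned
    genome with CTCF/cohesin anchors, AsiSI cut sites, damage-induced anchor
    enrichment, distance-decay contact matrices and junction libraries, so
    every analysis stage is testable with known injected effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
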