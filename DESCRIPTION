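Package: postdmr
Title: Tile-Based Calling of Tissue-Specific and Postnatally Demethylated Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from per-cytosine
    bisulfite counts using fixed-width genomic tiles with coverage filters.
    Implements a stringent tissue-specificity rule (a tile at least 50
    percentage points less or more methylated than the majority of a
    multi-tissue panel), classification of postnatal demethylation timing
    (prenatal, early or late postnatal) with a per-tile exact test, a
    label-replacement permutation test for the significance of a DMR set,
    promoter/intragenic/intergenic annotation, and enrichment of DMR-linked
    genes among postnatally upregulated genes via a two-proportion z-test.
    Ships a beta-binomial simulator of multi-tissue, multi-age RRBS-like
    datasets with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
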