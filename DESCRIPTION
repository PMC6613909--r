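Package: sesplice
Title: Super-Enhancer Proximity Screens and Splicing-Map Analysis for
    Candidate Master Splicing Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate tissue-specific master regulators of
    alternative splicing from super-enhancer proximity and characterizes
    their splicing programs. Implements GREAT-style basal-plus-extension
    regulatory domains and closest-TSS association of super-enhancers with
    genes, a multi-tissue RNA-binding-protein screen with expression-based
    ranking, spacer-constrained dimeric motif scanning (CACN1-12CAC) with
    region-thirds permutation enrichment and sliding-window RNA splicing
    maps, and post-processing of rMATS junction-count tables (PSI, event
    filtering, unique event identifiers, Venn overlaps, delta-PSI
    concordance, Z-scored hierarchical clustering). A synthetic-data module
    generates every input with known ground truth so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
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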