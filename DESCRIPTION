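Package: cladesig
Title: Column Signatures, Clade Coherence and Gene-Loss Mapping for Taxon Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for placing a fast-evolving taxon
    within a reference phylogeny. Implements a conservation-weighted column
    signature statistic for comparing two taxon groups across a multiple
    sequence alignment, with a resampling protocol for phylum-pair
    comparisons; a tree-coherence metric based on the minimum number of
    disjoint clades needed to cover a taxonomic group, with an allowance for
    intruding (horizontally transferred) sequences; 16S rRNA gap-frequency
    profiles and region-absence tests in reference coordinates; codon-usage
    matching of genes against modal usages by a within-family chi-squared
    test, with a native/non-native partition for detecting horizontally
    acquired genes; and single-origin (Dollo) parsimony mapping of binary
    trait losses onto a rooted tree. Seeded synthetic-data generators
    emulate each analysis input so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
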