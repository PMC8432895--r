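Package: syntenydecay
Title: Gene Order Conservation and Macrosynteny Decay Across Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies macrosynteny between chromosome-level genome
    assemblies from the positions of single-copy orthologs (BUSCO full
    tables) using the Gene Order Conservation (GOC) score, summarises
    chromosome-level synteny (gene assignment tables, chromosome
    intactness, ideogram link export), derives unit-height patristic
    distance matrices from a phylogeny, and fits linear, exponential
    and power-law models of synteny decay with phylogenetic distance
    using least squares with permutational F-statistic inference,
    including tests for group-specific decay rates. A genome
    rearrangement simulator (intra-chromosomal inversions and
    transpositions, rare inter-chromosomal translocations, gene loss)
    makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
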