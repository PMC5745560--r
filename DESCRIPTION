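Package: plastophylo
Title: Plastome Non-Coding Markers, Split Networks and Total-Evidence Parsimony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integral plastome phylogenomics toolkit. Extracts non-coding
    loci (introns and intergenic spacers) from annotated chloroplast genomes,
    scores their variability with a normalized divergence ratio and average
    uncorrected p-distances, and selects phylogenetically informative markers
    by threshold rules. Detects small structural rearrangements (palindromes,
    dispersed duplications, inversions, shared and unique indels). Builds
    Neighbour-Net circular split systems with nonnegative least-squares edge
    weights and fit statistics, and Z-closure supernetworks from partially
    overlapping gene trees. Performs total-evidence maximum parsimony over
    mixed DNA, binary, unordered and range-standardized continuous characters
    with exact branch-and-bound search, bootstrap and jackknife resampling,
    consistency and retention indices, and unambiguous synapomorphy mapping.
    A synthetic-data module simulates annotated plastome sets along a known
    tree with injected rearrangements and mixed matrices with planted
    synapomorphies, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'formats-io.R'
    'marker-selection.R'
    'mixed-matrix.R'
    'neighbor-net.R'
    'parsimony.R'
    'pipeline.R'
    'plastophylo-package.R'
    'rearrangements.R'
    'region-extraction.R'
    'resample.R'
    'simulate.R'
    'supernetwork.R'
    'synapomorphies.R'
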