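Package: genotax
Title: Genome-Based Taxon Demarcation with Similarity Indices and Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-based demarcation of bacterial genera and
    species. Computes the four similarity indices commonly used for
    prokaryotic taxonomy (fragment-based average nucleotide identity,
    average amino acid identity over reciprocal best hits, percentage of
    conserved proteins, and 16S rRNA gene identity), assembles them into
    labelled matrices, infers genus demarcation thresholds from the parting
    line between intra- and inter-genus value distributions, clusters
    genomes by average linkage, builds neighbor-joining trees from Kimura
    two-parameter distances, tests per-genus monophyly on unrooted trees,
    and fuses clustering and phylogeny into taxonomic reassignment
    proposals. A seeded synthetic genome-evolution generator with a planted
    genus/species hierarchy, per-branch substitution divergence, gene loss
    and controllable G+C content makes every pipeline stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    withr
SystemRequirements: BLAST+ (blastn, blastp, makeblastdb) for the default
    search backend of the similarity indices.
Config/testthat/edition: 3
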