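Package: yewpop
Title: Population Genetics and Cytonuclear Introgression Dynamics of Insular Yews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for chloroplast and nuclear haplotype data from
    island yew (Taxus) populations and their continental relatives. Provides
    alignment and sample-map handling with simple indel coding, per-population
    diversity statistics (haplotype diversity, nucleotide diversity,
    Watterson's theta), Weir-Cockerham F_IS and the Guo-Thompson exact test of
    Hardy-Weinberg equilibrium, pairwise Phi_ST and hierarchical
    Phi-statistic analysis of molecular variance with permutation tests,
    neighbour-joining population clustering, statistical-parsimony haplotype
    networks with haplogroup classification and introgression counting, a
    generation-recursive model of chloroplast versus nuclear introgression
    levels under pollen- or seed-mediated gene flow with an individual-based
    forward simulator, the chi-square-mixture likelihood-ratio test for
    post-split migration with isolation-with-migration unit conversions, and a
    structured-coalescent simulator that generates synthetic data sets
    emulating a three-taxon island-colonisation history.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
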