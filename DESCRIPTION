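Package: recombinv
Title: Recombination Landscapes in Inversion-Rich Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale reconstruction and analysis of recombination
    landscapes in genomes segregating polymorphic inversions. Builds
    simplified linkage maps from pedigree transmissions (pairwise LOD
    grouping, greedy seriation with 2-opt refinement, Haldane/Kosambi
    mapping functions), derives Marey maps and sliding-window
    recombination rates, counts crossovers as switches in phased
    parental haplotypes, tests inversion-mediated recombination
    suppression in heterokaryotypes (Wilcoxon and label-permutation
    tests), assesses TE/gene enrichment of inversions by interval
    permutation, and genotypes inversions in population panels via
    PCA clustering, windowed Weir-Cockerham Fst with threshold-based
    boundary calling, and linkage-disequilibrium screening. A seeded
    synthetic-data generator emulating a two-family pedigree design
    and a diverged-arrangement population panel provides truth-known
    inputs for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
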