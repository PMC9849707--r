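Package: haplodrift
Title: Temporal Mitochondrial Haplotype-Frequency Analysis with Drift Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing temporal change in mitochondrial haplotype
    frequencies from heterochronous (museum plus modern) samples. Reads aligned
    control-region sequences with per-sample collection years, masks
    unreplicated base calls with IUPAC ambiguity codes, collapses sequences
    into haplotypes (with gaps optionally treated as a fifth character state),
    recodes alignment gaps as binary presence/absence characters, and builds
    minimum-spanning haplotype networks with temporal layers. Provides a
    binomial resampling test of per-period haplotype-frequency change against a
    reference period (with a substitute frequency for haplotypes absent from
    the reference), its exact-binomial oracle, a meta-binomial test on the
    number of significant results, chi-square sampling-homogeneity tests,
    Chao1-anchored rarefaction/extrapolation of haplotype richness, and
    haplotype/nucleotide diversity indices. A haploid Wright-Fisher simulator
    with a piecewise census trajectory generates synthetic datasets with known
    truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
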