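Package: skimrep
Title: Comparative Repeat Landscape Profiling from Genome-Skimming Reads
Version: 0.1.0
Authors@R:
    person("Iris", "Calder", email = "iris.calder@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative analysis of repetitive DNA
    between related plant species from low-coverage ("genome skimming")
    paired-end reads. Provides a seeded synthetic-data generator (miniature
    genomes with LTR retrotransposons, solo-LTRs, DNA transposons, rDNA and a
    tandem satellite, plus organellar contamination), read preprocessing
    (full-length quality filtering, organelle removal, genome-proportion
    down-sampling), graph-based similarity clustering of reads into repeat
    clusters and mate-linked superclusters, lineage annotation against a
    packaged mini-reference with tandem-satellite monomer detection,
    genome-proportion and Mb/1C abundance statistics with between-species
    comparisons and regressions, tag-based solo-LTR quantification (the Rsf
    statistic), and maximum-likelihood ancestral genome-size reconstruction
    under Brownian motion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    ape,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
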