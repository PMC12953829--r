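Package: hgcscan
Title: Screening, Quantification and Ecological Profiling of Mercury-Methylation (hgcAB) Genes in Stratified Metagenomes
Version: 0.1.0
Authors@R: person("YBH", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and validate putative mercury-methylation marker
    genes (hgcA with its tandem partner hgcB) in assembled metagenomes, to
    quantify them as the percentage of genomes carrying the gene via
    genome-equivalent normalization, and to profile their distribution across
    a redox-stratified water column with free-living and particle-associated
    size fractions. Includes gene-tree rerooting and clade summaries,
    Kabsch superposition of predicted protein structures with iterative
    outlier-pair pruning, and a seeded synthetic-community generator with
    planted ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ape,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
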