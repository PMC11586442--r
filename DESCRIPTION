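Package: calcstrain
Title: Strain-Level and Community Analyses for Ancient Dental Calculus
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for strain-level analysis of ancient oral metagenomes:
    seeded simulation of deaminated (C-to-T / G-to-A) short-read alignments
    from synthetic bacterial genomes, read-end masking calibrated against
    damage, popANI/conANI strain-identity comparisons from base-count
    pileups, polymorphic-rate dN/dS screening for multi-strain samples,
    homozygous-SNP alignments with TN93 distances and neighbour-joining
    phylogenies (bootstrap, midpoint rooting, CADM concordance),
    cumulative-percent decay curves for preservation screening of
    oral-taxon content, and the FST-based FAVA statistic of abundance
    variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
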