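Package: hairpinox
Title: Strand-Resolved 5mC and 5hmC Analysis of Hairpin Bisulfite and
    Oxidative Bisulfite Amplicons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of hairpin bisulfite (BS) and oxidative
    bisulfite (oxBS) amplicon sequencing for strand-resolved DNA
    methylation and hydroxymethylation. Aligns hairpin read pairs against
    a composite top-linker-bottom reference with bisulfite-aware scoring,
    restores double-strand CpG dyad information per molecule, collapses
    PCR clones by the linker's unique molecular identifier, measures
    conversion rates from unmodified-C, 5mC and 5hmC linker controls, and
    estimates 5hmC levels, dyad symmetry and Dnmt/Tet enzyme efficiencies
    with a nine-state hidden Markov model of methylation maintenance,
    de novo methylation and hydroxylation over cell divisions. A
    seeded simulator generates synthetic hairpin read sets with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ggplot2,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
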