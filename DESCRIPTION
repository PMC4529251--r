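Package: hybridscan
Title: Phylogenomic Detection of Whole-Genome Duplication and Ancient
    Hybridization Signals from Phylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to interrogate collections of gene trees (phylomes) for
    the footprints of whole-genome duplication and interspecies
    hybridization. Detects duplication nodes with the species-overlap
    algorithm, maps their relative ages onto a reference species tree, and
    computes per-branch duplication densities; provides LCA reconciliation
    as an independent mapper and cross-method agreement summaries.
    Classifies each seed sequence's sister clade against two putative
    parental lineages (A/B/C and the nine-way ohnolog-pair scheme),
    quantifies ohnolog sequence divergence (Kimura protein distance,
    normalized alignment score, Kolmogorov-Smirnov population comparison),
    and scans gene-order tables for clade-specific synteny breaks and their
    inheritance in polyploid genomes. A seeded simulator generates phylomes
    under no-event, autopolyploidy, and hybridization scenarios with
    stochastic gene loss, site-rate-heterogeneous protein evolution, long
    branch acceleration, and partial gene conversion, and a distance-based
    neighbor-joining stage closes the simulate-infer-map loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
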