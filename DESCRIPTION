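Package: haploclone
Title: Clone-Library Haplotype Filtering, Diversity and Host-Association
    Analysis for Endosymbiont Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cloned amplicon libraries of maternally
    inherited endosymbionts (e.g. Wolbachia groEL clone libraries from
    tsetse flies). Classifies clone sequences as genuine variants or PCR
    artifacts under a Poisson polymerase-error model, screens for
    within-host recombinants with a permutation test on maximal
    mismatch-free runs over polymorphic sites, computes haplotype and
    nucleotide diversity at any grouping level, builds statistical-parsimony
    haplotype networks with a probability-of-parsimony connection limit,
    partitions sequence variation among host mitochondrial haplogroups by
    one-level AMOVA with permutation p-values, and tests
    symbiont-lineage/host-haplogroup association by randomization and exact
    binomial tests. Includes a seeded synthetic clone-library generator
    with full ground truth so that every stage can be validated against
    known simulation parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
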