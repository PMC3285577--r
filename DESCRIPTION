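Package: mslineage
Title: Cell Lineage Reconstruction from Somatic Microsatellite Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective single-cell lineage analysis from somatic
    microsatellite repeat-number mutations. Implements the symmetric
    stepwise mutation model (per-allele per-division rate), maximum
    likelihood pairwise division distances, neighbor-joining lineage trees
    rooted at the median pseudo-zygote, per-cell depth (divisions since the
    zygote), hypergeometric clade-enrichment tests with FDR control and
    nested-subtree pruning, and cohort-level statistics (depth versus age
    with permutation and bootstrap inference, ovariectomy contrasts, the
    production-line resampling test, spontaneous-mutation tallies, and a
    mutation-rate sensitivity sweep). A generative simulator emulates the
    study design end to end: binary division genealogies, diploid
    microsatellite panels with strain-distinguishable alleles, allelic
    dropout, PCR repeats, progenitor-restricted populations and post-natal
    renewal or production-line depth scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
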