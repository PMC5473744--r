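Package: ccimpute
Title: Probabilistic Genotype and Diplotype Imputation for Multiparental
    Recombinant Inbred Strains
Version: 0.1.0
Authors@R: person("CC", "Imputation Maintainers",
    email = "maintainers@example.org", role = c("aut", "cre"))
Description: Haplotype-based imputation of unphased genotype and diplotype
    probability distributions for recombinant inbred strains (such as the
    Collaborative Cross) from founder sequencing calls and sparse marker
    diplotype probabilities. Linearly interpolates marker diplotype
    distributions to any variant position, propagates founder genotype
    uncertainty and residual heterozygosity through Mendelian transmission,
    simulates genotype and diplotype distributions for F1 crosses between
    any two strains, attaches per-transcript functional consequences while
    preserving probabilistic state, and persists results in a per-chromosome
    store answering genotype, diplotype and cross queries with
    maximum-likelihood, probability-threshold, zygosity and consequence
    restrictions. Includes a fully ground-truthed synthetic data generator
    (founder VCF, marker probabilities, exons, consequences) so the entire
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
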