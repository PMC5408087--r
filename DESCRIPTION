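Package: tunapopgen
Title: Population-Genomic Differentiation and Isolation-with-Migration
    Demography for Two-Ocean Fish Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome population-genomic analysis of weakly
    differentiated marine populations: a two-population isolation-with-migration
    (IM) coalescent simulator with synthetic variant-call fixtures; the
    two-caller variant-filter cascade (callset intersection, GATK-style hard
    filters, genotype masking, heterozygote-excess exact Hardy-Weinberg test,
    minor-allele and missingness filters, LD pruning); Weir-Cockerham and Nei
    fixation indices with locus bootstrap and sequential Bonferroni correction;
    folded joint minor-allele site-frequency spectra with fractional tie
    weights; IM demographic inference by simulated-SFS composite likelihood;
    mutation-rate calibration from interspecific divergence; PSMC input
    encoding and output scaling; and transversion-collapsed haplotype
    genealogy graphs from parsimony trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    vcfR,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
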