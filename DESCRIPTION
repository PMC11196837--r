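Package: apiadmix
Title: Racial Ancestry of Honey Bee Colonies from Pooled SNPs and mtDNA Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates African (A), Western European (M) and Eastern European (C)
    racial ancestry of Apis mellifera colonies. Nuclear ancestry is estimated by
    maximum likelihood from pooled-worker reference-allele counts at ancestry-
    informative SNPs under a three-way admixture model with binomial sampling of
    the 40-allele worker pool. Maternal ancestry is classified from COI-COII
    intergenic mtDNA sequences against lineage reference sequences, with haplotype
    deduplication, a parsimony-style haplotype network, and apiary-level
    mitochondrial Africanization. Mitochondrial and nuclear ancestry proportions
    are compared through Wald confidence intervals at lineage-appropriate
    effective allele counts. A colony simulator (queen plus drone matings,
    pooled workers) provides ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
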