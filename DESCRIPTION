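Package: lekscape
Title: Fine-Scale Population Genomic Structure of Lek-Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying fine-scale genetic structure
    in lek-breeding populations from genotyping-by-sequencing data. Starting
    from genotype likelihoods, a hierarchical Bayesian model estimates allele
    frequencies and posterior genotype dosages per locus; downstream modules
    provide ordination-based structure inference (PCA, Procrustes rotation
    onto geography, discriminant analysis of principal components, redundancy
    analysis, PERMANOVA), pairwise differentiation statistics (Weir-Cockerham
    F_ST with permutation tests, Nei's standard genetic distance,
    neighbor-joining trees), landscape-resistance models of genetic distance
    (least-cost paths over resistance rasters, Mantel tests, multiple
    regression on distance matrices), and a locus-subsampling precision
    analysis. A synthetic-data generator emulating a hierarchical lek /
    lek-complex sampling design makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    ape,
    igraph,
    geosphere,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
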