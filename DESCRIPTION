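Package: niptprs
Title: Maternal Polygenic Risk Scores from Low-Coverage Prenatal cfDNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference pipeline for estimating maternal polygenic
    risk scores (PRS) from low-coverage cell-free DNA (cfDNA) sequencing of the
    kind produced by non-invasive prenatal testing. Provides a copying-mosaic
    simulator for phased reference haplotype panels with linkage disequilibrium,
    mother-fetus genotype pairs, and cfDNA pileup mixtures at configurable
    coverage and fetal fraction with origin-specific fragment-length
    distributions; forced genotyping via a binomial genotype-likelihood model;
    maternal genotype imputation with a diploid Li-Stephens haplotype-copying
    hidden Markov model; PRS computation against PGS Catalog scoring files; and
    orchestrated experiments quantifying how coverage, fetal fraction,
    fragment-length filtering and scoring-panel size affect PRS accuracy and
    high-risk percentile classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
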