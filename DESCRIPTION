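Package: hybridscan
Title: Diagnostic SNP Panels, Hybrid-Class Assignment and Population
    Structure for Translocated Wrasse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting aquaculture-mediated translocation of
    corkwing wrasse (and similar two-cluster systems) from biallelic SNP
    genotypes: genotype QC filters, Weir-Cockerham F-statistics with
    Monte-Carlo significance, Hardy-Weinberg exact tests by complete
    enumeration, allelic richness, hierarchical AMOVA, ranked-FST
    diagnostic panel design, Mendelian simulation of six hybrid classes
    from diverged reference populations, a NewHybrids-style six-class
    Gibbs classifier with calibrated efficiency/accuracy/power
    evaluation, EM admixture proportions with Evanno delta-K, genotype
    PCA, and sigmoid geographic cline fitting with AIC model choice and
    two-log-likelihood support limits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
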