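Package: crossgp
Title: Multi-Breed and Crossbred Genomic Prediction with Weighted GBLUP
    and a Mixture-Prior Bayesian SNP Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation of genomic prediction strategies for
    a two-breed dairy population (Holstein-Friesian and Jersey) with
    crossbred cows. Simulates diverged breeds and first/second generation
    crosses, deregressed-proof (DRP) phenotypes with record- or
    daughter-count derived weights, and reference/validation designs;
    provides marker QC (MAF filtering, LD pruning), VanRaden genomic
    relationship matrices, GRM-PCA and maximum-likelihood admixture
    breed-composition estimation, weighted GBLUP via the mixed-model
    equations, a four-component mixture-prior Bayesian SNP-effect model
    (EM warm start plus Gibbs sampling, multiple averaged chains), and an
    experiment harness scoring accuracy (Pearson correlation of GEBV with
    DRP) and bias (regression of DRP on GEBV) per validation breed group,
    including breed-proportion weighted-average GEBV for crossbreds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
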