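Package: hybridGP
Title: Multi-Kernel Genomic Prediction of Hybrid Performance Across Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of single-cross hybrid performance from
    parental inbred markers in multi-environment trials. Builds genomic
    relationship matrices from inbred SNP panels, assembles general
    combining ability (GCA), specific combining ability (SCA) and
    genotype-by-environment interaction covariance kernels, and fits
    multi-kernel Bayesian GBLUP models by Gibbs sampling with
    scaled-inverse-chi-squared variance priors. Includes the CV2/CV1/CV0
    cross-validation schemes used to benchmark hybrid prediction,
    optional augmentation of calibration sets with parental inbred
    phenotypes, and a synthetic multi-environment trial generator that is
    the exact probabilistic twin of the fitted models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
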