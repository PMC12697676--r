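Package: gLDM
Title: Lesion-Deficit Mapping with and without Domain-General Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how domain-general cognition (g) shapes
    lesion-deficit mapping. Implements confirmatory bifactor and
    correlated-factors models fitted by full-information maximum
    likelihood, mass-univariate lesion-behavior mapping with
    permutation-based family-wise error correction, structural and
    functional lesion network mapping against normative connectome
    stand-ins, partial least squares mapping, and a permutation test
    comparing the spatial inter-correlation of domain-specific maps
    between cognitive models. A synthetic-cohort generator with known
    ground truth supports calibration and recovery studies, and a
    config-driven pipeline reproduces the full study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    mixOmics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
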