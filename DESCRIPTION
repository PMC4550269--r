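Package: voxmediate
Title: Voxel-Wise Mediation and Suppression Analysis of Resting-State
    Regional Homogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for imaging-genetics mediation analysis linking a weighted
    multi-locus gene score, regional homogeneity (Kendall's coefficient of
    concordance) of resting-state 4D volumes, and a personality phenotype.
    Implements temporal preprocessing (volume discarding, linear detrending,
    ideal band-pass filtering, nuisance regression), head-motion summaries,
    voxel-wise three-step mediation mapping with cluster-extent correction by
    Monte-Carlo simulation of smooth Gaussian fields and by random-gene-score
    permutation, and an ROI-level path model quantifying mediation or
    suppression with bootstrap confidence intervals and leave-one-out
    validation. A synthetic-data module generates genotypes, phenotypes,
    motion traces and 4D volumes with the assumed causal structure so the
    whole pipeline is testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
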