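Package: thermoasr
Title: Ancestral Optimal Growth Temperature Inference from Protein
    Composition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the thermal preferences of ancestral microorganisms from
    protein sequence composition. Computes the CvP bias (charged minus polar
    amino-acid proportions) of aligned protein sequences, calibrates a linear
    CvP to optimal-growth-temperature (OGT) model from extant taxa with
    corrections for over-represented mesophiles and psychrophile outliers,
    roots gene trees by the minimal ancestor deviation (MAD) criterion,
    reconstructs marginal maximum-likelihood ancestral sequences under
    empirical amino-acid substitution models with discrete-gamma rate
    heterogeneity, and predicts OGTs at every internal node. Ships a
    synthetic-data generator that evolves sequence composition along a
    phylogeny following a latent temperature trajectory, so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    Matrix,
    withr
Config/testthat/edition: 3
biocViews: Phylogenetics, Software, SequenceAnalysis
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'cvp.R'
    'calibration.R'
    'model.R'
    'likelihood.R'
    'asr.R'
    'mad.R'
    'simulate.R'
    'pipeline.R'
    'thermoasr-package.R'
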