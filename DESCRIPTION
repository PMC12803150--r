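Package: regenkit
Title: Quantitative Toolkit for Tooth-Regeneration Single-Nucleus RNA-Seq Studies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the quantitative core of a pulse-chase tooth-plucking
    regeneration study in polyphyodont fish: pulse-chase tooth-gain statistics
    (paired t, one-way ANOVA with Tukey-Kramer), barcode quality control and
    log-normalization/HVG/PCA/kNN preprocessing for single-nucleus RNA-seq,
    pooled-genotype deconvolution by a binomial-mixture EM with a dual-run
    consensus rule, cross-species cell-type homology scoring on a
    homology-weighted joint embedding with a permutation null,
    developmental-potential scoring with directed transition fields and
    Moran's I trajectory-gene testing, condition and time-course differential
    expression, and mass-action ligand-receptor communication networks with
    plucked-versus-control differential comparison. A synthetic-data module
    generates every input with known ground truth so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'regenkit-package.R'
    'AllClasses.R'
    'communication.R'
    'deconvolution.R'
    'differential.R'
    'homology.R'
    'io.R'
    'potential.R'
    'preprocess.R'
    'synthetic.R'
    'toothgain.R'
    'utils.R'
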