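Package: sparsegrn
Title: Sparse Reconstruction of Gene Regulatory Networks from
    Steady-State Perturbation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers sparse gene regulatory networks from steady-state
    perturbation expression data by casting each gene's incoming
    regulation as an underdetermined sparse linear regression.
    Implements the stagewise modified orthogonal matching pursuit
    (SmOMP) solver with false-alarm-control thresholding, iterative
    outlier-deletion noise-variance estimation and true-positive-rate
    support refinement, alongside plain stagewise OMP (StOMP) and a
    total-least-squares baseline.  Ships a synthetic benchmark
    generator with power-law column sparsity, readers for DREAM-style
    steady-state tables and gold standards, ROC/PR evaluation with
    permutation-based significance scoring, and empirical
    phase-transition experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
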