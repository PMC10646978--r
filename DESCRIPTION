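Package: immunoloop
Title: Active-Learning Screening of Small-Molecule Innate-Immune Modulators
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Machine-learning-guided screening pipeline for small-molecule
    immunomodulators delivered alongside pattern-recognition-receptor agonists.
    Provides molecular ingestion and SELFIES-style tokenization, a variational
    autoencoder embedding at configurable scale, per-goal Gaussian-process
    surrogates over the latent space, multi-objective Kriging-believer batched
    Bayesian selection with Expected Improvement, Bhattacharyya-distance and
    cross-validated-error convergence monitors, high-throughput-screening plate
    normalization with replicate error propagation and confluency-based
    viability filtering, LASSO fragment design-rule extraction, and a synthetic
    plate-level screening oracle with a planted structure-activity relationship
    for end-to-end testing without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with rdkit, available as 'python' on PATH
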