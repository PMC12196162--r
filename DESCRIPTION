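Package: senoscreen
Title: Imbalance-Aware Dual-Model Virtual Screening for Senolytic Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds senolytic-activity predictors from small, highly imbalanced
    bioactivity datasets and screens compound libraries with them. Provides
    curation of labelled compound tables with a Tanimoto similarity filter for
    the negative class, pluggable molecular features (extended-connectivity
    fingerprints, a frozen 200-descriptor vector, FP2 via an optional Open
    Babel backend, and dense molecular embeddings behind an embedder
    contract), minority oversampling that exploits batch-to-batch embedding
    variability, a dual predictor (RBF support vector machine with balanced
    class weights plus a single-hidden-layer neural network ensemble trained
    with Adam, dropout and early stopping), distance-to-model applicability
    domain gating, consensus screening with structural-novelty annotation, and
    hypergeometric source (herb) enrichment with Benjamini-Hochberg
    correction. A synthetic compound-library generator with planted scaffolds
    and a stochastic mock embedder make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    withr
Suggests:
    ChemmineR,
    ChemmineOB,
    pROC,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the RDKit package on the PATH as
    'python' (used for SMILES canonicalization, Morgan fingerprints and
    molecular descriptors).
Config/testthat/edition: 3
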