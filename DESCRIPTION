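Package: amlclass
Title: Molecular Classification, Risk Stratification and Multi-State
    Outcome Modelling for Acute Myeloid Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A unified framework for genomic classification and risk
    stratification of acute myeloid leukemia (AML). Implements a
    deterministic 16-class hierarchical classifier over coded
    cytogenetic lesions and a 32-gene mutation panel, TP53 allelic-state
    annotation, ELN 2017 reference risk stratification, a proposed
    3-tier class-based risk score with FLT3-ITD shift rules, a six-state
    multi-state survival model with Aalen-Johansen transition
    probabilities, per-transition Cox models and per-covariate
    contributing-factor decomposition, Dirichlet-process mixture
    clustering of binary lesion matrices, a survival-model comparison
    harness (IPCW concordance index, permutation feature importance),
    and a synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
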