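Package: pasdrift
Title: Pathway Activation Strength Scoring and Signalome Drift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores per-sample signaling pathway activation from
    case-versus-reference gene expression matrices (Pathway Activation
    Strength, PAS: the sum over member genes of activator/repressor role
    coefficient times a differential-expression significance flag times the
    log10 case-to-normal expression ratio), then compares pathway activation
    between donor age groups, progeria (HGPS) fibroblasts, or cell-passage
    groups using standardized-margin equivalence t- and F-tests with
    noncentral-F critical values. Includes correlation clustering, PCA
    embedding and passage-ordered drift classification of PAS profiles, and
    a synthetic multi-dataset expression-study generator with known
    ground-truth pathway regulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
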