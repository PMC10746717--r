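Package: uwshap
Title: Uncertainty-Weighted Shapley Attributions for Tear-Proteome Severity Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Biomarker discovery from label-free tear-film proteomics by model
    explanation. Implements preprocessing of relative protein quantification
    tables (contaminant removal, special-value encoding, log transform and
    standardization), gradient-boosted stump classifiers of meibomian gland
    dysfunction severity, exact Shapley feature attributions for stump
    ensembles with a subset-enumeration oracle, an uncertainty weighting
    scheme that rescales attributions by predicted class probabilities, a
    differential-abundance comparator (per-protein one-way ANOVA, fold change,
    Benjamini-Hochberg FDR), and a synthetic cohort simulator with
    abundance-dependent missingness for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
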