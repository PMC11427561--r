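Package: diametrics
Title: Entrapment Fidelity Metrics and Quantification Workflows for
    Low-Input DIA Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing and evaluation of data-independent acquisition
    (DIA) proteomics experiments in which a foreign "entrapment" proteome
    (e.g. E. coli spiked into human samples) is used to estimate the fidelity
    of identification and of match-between-runs identity transfer. Implements
    per-replicate false-positive and false-transfer rates (including the
    degenerate-count convention), ROC analysis over search-engine q-values,
    Szymkiewicz-Simpson overlap and Jaccard similarity of identification
    sets, q-value and contaminant filtering of long-format precursor report
    tables, exclusion of matching-enhancer runs followed by ion-trace
    re-normalization and protein summarization, quantitative quality metrics
    (coefficients of variation, abundance-binned data completeness, spike
    ratio recovery, sample correlation, PCA, dynamic range), single-cell
    differential expression, imputation and protein co-variation clustering,
    and a synthetic two-proteome report generator with full ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
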