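Package: hrdact
Title: Homologous Recombination Deficiency and Immune Activation Analysis
    for Chemotherapy Response in Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise homologous recombination deficiency (HRD)
    from allele-specific copy-number segments (LOH, telomeric allelic
    imbalance and large-scale transition counts), fit trinucleotide
    mutational-signature exposures, score single-sample immune pathway
    activity, derive an HRD-related transcriptional signature with its
    prognostic-score equations, and combine HRD with immune activation into
    a responder classifier for anthracycline/cyclophosphamide/taxane (ACT)
    chemotherapy. Includes a synthetic multi-omic cohort generator with
    planted ground truth so every stage of the analysis is testable without
    access to patient-level data, plus the survival and association
    statistics (Kaplan-Meier/log-rank, Cox models, likelihood-ratio tests,
    time-fixed ROC, Fisher and rank tests with permutation variants) used
    throughout the workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
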