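Package: proteofunnel
Title: Label-Free Proteomics Differential Abundance and Biomarker Funnel for
    Amyloid Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for label-free quantification (LFQ) brain
    proteomics in amyloid-pathology mouse studies: missing-value reliability
    filtering without imputation, empirical-Bayes batch adjustment of log10
    intensities, moderated differential abundance with within-animal
    correlation and interaction contrasts, classification of proteins whose
    fold-change trajectories track amyloid-beta aggregate accumulation,
    cross-species concordance against human Alzheimer proteomes through an
    ortholog map, an auditable biomarker candidate-selection funnel, and ROC
    evaluation of a cerebrospinal-fluid analyte. Ships a synthetic-data
    generator that emulates the two-tissue, three-age, two-genotype study
    design with intensity-dependent missingness so the whole pipeline runs
    and tests without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    sva,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
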