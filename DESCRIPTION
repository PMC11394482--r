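Package: cmpnomics
Title: Multi-Omics Isolation of Membrane-Progesterone-Receptor-Specific
    CCM1 Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for isolating membrane progesterone receptor
    (mPR)-specific, CCM1-mediated signals from paired proteomic (iBAQ
    intensity) and RNA-seq (count) data across CCM1 genotypes and
    progesterone treatments. Provides uncorrected two-sample t-test
    differential expression with up/down classification, Venn set-algebra
    partitioning with explicit percentage denominators, a two-step
    filtration that removes CCM1-dosage-dependent and non-mPR "antagonist"
    responses, hypergeometric gene-set over-representation analysis with
    GeneRatio and Benjamini-Hochberg adjustment, and a cost-sensitive
    support-vector-machine transcription-factor predictor with stratified
    cross-validation and consensus candidate calling. A synthetic-data
    module generates every input the pipeline consumes, with planted
    effects for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
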