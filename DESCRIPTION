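Package: estromeld
Title: Cross-Study Meta-Analysis of Estrogen-Receptor Modulator Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes heterogeneous differential-expression comparisons of
    estrogen-receptor (ER) modulator treatments and endocrine-resistance
    models into regulatory percentiles in [-100, 100], and computes
    cross-comparison consensus, divergence, and enrichment statistics:
    heterogeneity (CV^2) contrasts, correlation/clustering of drug and
    cell-line response profiles, bidirectional and consensus gene calls,
    per-gene mixed-effect regression on experimental covariates, preranked
    gene-set enrichment with permutation NES/FDR, Fisher over-representation,
    single-sample signature scoring with logistic/ROC cohort classification,
    Oncotype DX weighted impact, and ChIP-seq gained-peak regulatory-potential
    scoring around transcription start sites. A synthetic-data generator with
    serialized ground truth emulates the statistical structure of the curated
    experiment registry so the full pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
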