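Package: tlscore
Title: Tertiary Lymphoid Structure Gene-Signature Scoring for Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a tertiary lymphoid structure (TLS) activity score for bulk
    tumor transcriptomes from a 23-gene TLS-related signature. Implements the
    full derivation chain: FPKM-to-TPM conversion and empirical-Bayes batch
    correction, subsampled consensus clustering with PAC-based selection of the
    cluster number, moderated-t differential expression, univariate Cox
    screening of prognostic genes, a PCA score defined as the difference of the
    first two principal-component scores, and maximally selected log-rank
    dichotomization into high/low prognostic groups. Companion modules provide
    rank-based single-sample enrichment (ssGSEA) with ESTIMATE-style
    stromal/immune/purity scores, mutation-burden integration, and single-cell
    QC plus binned-control module scoring. A synthetic-cohort generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    limma,
    sva,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
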