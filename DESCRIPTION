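Package: metasurg
Title: Longitudinal Muscle Methylome-Transcriptome Integration After Metabolic Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal integration of skeletal-muscle gene
    expression, EPIC-style DNA methylation and clinical phenotypes collected
    before and 2, 12, 24 and 52 weeks after metabolic surgery. Implements
    probe quality control (sex-chromosome and SNP exclusion rules),
    per-feature differential statistics (Welch and paired t-tests with
    Benjamini-Hochberg adjustment of methylation results and delta-beta
    effect sizes), temporal classification of genes into transient, constant
    and late-response patterns, promoter/gene-body direction-concordance
    rules linking differential methylation to differential expression,
    candidate-gene filtering, CpG-island and gene-region enrichment tests,
    reprogramming enrichment of transiently expressed genes, Pearson
    correlation of omics features with clamp-derived phenotypes, clinical
    insulin-sensitivity indices (Adipo-IR, M-value, delta-RQ, RCR/LCR), and
    a synthetic cohort generator that plants known effects for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
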