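Package: tmeprofiler
Title: Tumor-Microenvironment Immune Infiltration Scoring and Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-microenvironment (TME) immune infiltration from
    bulk gene-expression matrices and derives a prognostic TME score. Provides
    single-sample gene-set enrichment (ssGSEA) over immune-cell signatures,
    ESTIMATE-style immune/stromal scores, resampling consensus clustering with
    PAM (k-medoids) and delta-area optimal-k selection, empirical-Bayes
    moderated differential expression, univariate Cox prognostic filtering,
    per-gene-cluster PCA signature scores combined into a signed TME score,
    survival dichotomization by maximally selected log-rank statistics, and the
    surrounding survival and association tests. A synthetic-cohort generator
    with two latent immune phenotypes, phenotype-linked expression shifts,
    survival hazards and immunotherapy-response labels makes the full pipeline
    testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
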