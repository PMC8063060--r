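#!/usr/bin/env Rscript
# Score each sample for the 28 immune-cell signatures with ssGSEA and build
# ESTIMATE-style immune/stromal/combined infiltration scores.

library(tmeprofiler)

expr <- read_expression("results/cohort/expression.tsv")
sigs <- read_gmt("results/cohort/signatures.gmt")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

enr <- ssgsea_scores(expr, sigs, alpha = 0.25)
write_matrix_tsv(enr$scores, "results/enrichment/ssgsea_scores.tsv",
                 id_column = "gene_set")

# the first two signatures stand in for immune/stromal reference sets
est <- estimate_scores(expr, sigs$sets[[1]], sigs$sets[[2]])
write.table(est, "results/enrichment/estimate_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("ssGSEA: %d signatures x %d samples; score range [%.2f, %.2f]",
                nrow(enr$scores), ncol(enr$scores),
                min(enr$scores), max(enr$scores)))
message(sprintf("ESTIMATE-style combined score: median %.1f (IQR %.1f-%.1f)",
                median(est$estimate_score),
                quantile(est$estimate_score, 0.25),
                quantile(est$estimate_score, 0.75)))
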