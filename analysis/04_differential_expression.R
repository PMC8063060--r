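#!/usr/bin/env Rscript
# Moderated differential expression between the two TME phenotypes, the DEG
# filter (FDR < 0.01, |logFC| > 1), and a gene-set over-representation check
# of the DEGs against the immune-cell signature collection.

library(tmeprofiler)

expr <- read_expression("results/cohort/expression.tsv")
labels <- read.delim("results/tme_clusters/tme_cluster_assignments.tsv")
sigs <- read_gmt("results/cohort/signatures.gmt")
dir.create("results/diffexp", showWarnings = FALSE, recursive = TRUE)

expr <- expr[, labels$sample_id]
de <- moderated_de(expr, labels$tme_cluster)
write.table(de[, c("gene", "logFC", "t", "p_value", "adj_p")],
            "results/diffexp/differential_expression.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("moderated fit: prior df %.1f, prior variance %.3f (%s)",
                attr(de, "d0"), attr(de, "s0_sq"), attr(de, "reference")))

degs <- filter_degs(de, adj_p_max = 0.01, min_abs_lfc = 1)
writeLines(degs, "results/diffexp/degs.txt")
message(sprintf("%d DEGs of %d genes pass FDR < 0.01 and |logFC| > 1",
                length(degs), nrow(de)))

enrich <- ora(degs, sigs, rownames(expr))
write.table(enrich, "results/diffexp/deg_ora.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("ORA: %d of %d signatures over-represented at adjusted p < 0.05",
                sum(enrich$adj_p < 0.05), nrow(enrich)))
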