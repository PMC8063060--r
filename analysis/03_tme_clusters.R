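#!/usr/bin/env Rscript
# Partition samples into TME phenotypes by resampling consensus clustering
# (PAM on the ssGSEA profile), check the cluster number diagnostics, and test
# whether the two phenotypes differ in survival and per-signature enrichment.

library(tmeprofiler)

seed <- 1L
enr <- read_expression("results/enrichment/ssgsea_scores.tsv")  # sets x samples
clinical <- read_clinical("results/cohort/clinical.tsv")
dir.create("results/tme_clusters", showWarnings = FALSE, recursive = TRUE)

cc <- consensus_cluster(t(enr), consensus_params(k_range = 2:4,
                                                 n_resamples = 100,
                                                 seed = seed))
write_consensus_result(cc, "results/tme_clusters")
message(sprintf("optimal k by consensus crispness: %d (PAC: %s)",
                cc$optimal_k, paste(round(cc$pac, 3), collapse = ", ")))

labels <- cc$labels[["2"]]
# orient so cluster 1 is the immune-high phenotype
m <- tapply(colMeans(enr), labels, mean)
if (which.max(m) != 1) labels <- 3L - labels
write.table(data.frame(sample_id = names(labels), tme_cluster = labels),
            "results/tme_clusters/tme_cluster_assignments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cl <- clinical[match(names(labels), clinical$sample_id), ]
lr <- logrank_test(labels, cl$os_time, cl$os_event)
message(sprintf("survival: log-rank chi-square %.2f (p = %.3g) between TME clusters",
                lr$chi_square, lr$p))

# per-signature distribution across clusters (Kruskal-Wallis-routed)
per_sig <- do.call(rbind, lapply(rownames(enr), function(s) {
  gc <- compare_groups(enr[s, ], labels)
  data.frame(signature = s, method = gc$method, statistic = gc$statistic,
             p = gc$p)
}))
per_sig$adj_p <- bh_adjust(per_sig$p)
write.table(per_sig, "results/tme_clusters/signature_by_cluster_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d signatures differ between clusters at FDR 0.05",
                sum(per_sig$adj_p < 0.05), nrow(per_sig)))
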