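#!/usr/bin/env Rscript
# From DEGs to the per-patient TME score: univariate-Cox prognostic filter,
# consensus gene clusters, PC1 signature score per cluster, the signed sum
# oriented so that a high score marks good prognosis, and dichotomization
# into high/low score groups.

library(tmeprofiler)

seed <- 1L
expr <- read_expression("results/cohort/expression.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
degs <- readLines("results/diffexp/degs.txt")
dir.create("results/tme_score", showWarnings = FALSE, recursive = TRUE)

prog <- filter_prognostic(degs, expr, clinical, p_max = 0.05)
write.table(prog$fits, "results/tme_score/prognostic_gene_fits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d DEGs are prognostic at Cox p < 0.05",
                length(prog$genes), length(degs)))

z <- expr[prog$genes, , drop = FALSE]
z <- (z - rowMeans(z)) / apply(z, 1, sd)
gcc <- consensus_cluster(z, consensus_params(k_range = 2:4, n_resamples = 100,
                                             distance = "one_minus_pearson",
                                             seed = seed + 1L))
glab <- gcc$labels[[as.character(gcc$optimal_k)]]
write.table(data.frame(gene = names(glab), gene_cluster = glab),
            "results/tme_score/gene_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("gene clusters: optimal k = %d (sizes: %s)", gcc$optimal_k,
                paste(table(glab), collapse = ", ")))

pc1 <- lapply(split(names(glab), glab), function(gs) pc1_signature(expr, gs))
names(pc1) <- paste0("gene_cluster_", names(pc1))
cl <- clinical[match(colnames(expr), clinical$sample_id), ]
hr <- vapply(pc1, function(v)
  cox_univariate(v, cl$os_time, cl$os_event)$HR, numeric(1))
message("cluster-level hazard ratios: ",
        paste(sprintf("%s %.2f", names(hr), hr), collapse = ", "))

raw <- tme_score(pc1, hr)
orient <- if (cox_univariate(raw, cl$os_time, cl$os_event)$beta > 0) -1 else 1
score <- orient * raw
message(sprintf("orientation %+d applied so that a high score is protective",
                orient))

dich <- dichotomize_score(score, cl$os_time, cl$os_event, method = "median")
scored <- data.frame(sample_id = cl$sample_id, as.data.frame(pc1),
                     tme_score = unname(score), score_group = dich$groups)
write.table(scored, "results/tme_score/tme_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("median-split cutpoint %.3f: %d high vs %d low",
                dich$cutpoint, sum(dich$groups == "high"),
                sum(dich$groups == "low")))
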