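#!/usr/bin/env Rscript
# Outcome analysis of the TME score groups: Kaplan-Meier curves, log-rank
# test, univariate and age-adjusted Cox models, recovery of the latent
# phenotype, and the association between score and immunotherapy response.

library(tmeprofiler)

clinical <- read_clinical("results/cohort/clinical.tsv")
scored <- read.delim("results/tme_score/tme_scores.tsv")
truth <- read.delim("results/cohort/truth.tsv")
dir.create("results/outcome", showWarnings = FALSE, recursive = TRUE)

cl <- clinical[match(scored$sample_id, clinical$sample_id), ]
groups <- factor(scored$score_group, levels = c("low", "high"))

for (g in levels(groups)) {
  km <- km_estimate(cl$os_time[groups == g], cl$os_event[groups == g])
  write.table(km, sprintf("results/outcome/km_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
lr <- logrank_test(groups, cl$os_time, cl$os_event)
message(sprintf("log-rank high vs low: chi-square %.2f, p = %.3g",
                lr$chi_square, lr$p))

covars <- data.frame(tme_score_high = as.integer(groups == "high"),
                     age = cl$age)
cox <- cox_multivariate(covars, cl$os_time, cl$os_event)
write.table(cox[, c("term", "HR", "lo95", "hi95", "p")],
            "results/outcome/cox_models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("age-adjusted HR for high TME score: %.2f [%.2f, %.2f], p = %.3g",
                cox$HR[1], cox$lo95[1], cox$hi95[1], cox$p[1]))

ari <- adjusted_rand_index(groups, truth$phenotype[match(scored$sample_id,
                                                         truth$sample_id)])
message(sprintf("high/low score groups vs latent hot/cold phenotype: ARI %.2f",
                ari))

assoc <- score_response_association(scored, cl$response)
rep <- data.frame(test = c("wilcoxon_score_by_response",
                           "chisq_scoregroup_by_response"),
                  statistic = c(assoc$wilcoxon$statistic, assoc$chisq$chi_square),
                  p = c(assoc$wilcoxon$p, assoc$chisq$p))
write.table(rep, "results/outcome/response_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("response association: Wilcoxon p = %.3g; chi-square p = %.3g",
                assoc$wilcoxon$p, assoc$chisq$p))
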