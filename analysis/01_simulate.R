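#!/usr/bin/env Rscript
# Simulate the study cohort: 120 tumors, 28 immune-cell signatures inside a
# 1000-gene background, two latent immune phenotypes (hot/cold) with a
# 3 log2-unit signature shift, twofold excess hazard in cold tumors, ~30%
# censoring, and response labels linked to the phenotype.

library(tmeprofiler)

seed <- 1L
out <- "results/cohort"

params <- cohort_params(seed = seed)
cohort <- generate_cohort(params)
write_cohort(cohort, out)

null_cohort <- generate_null_cohort(params)
write_cohort(null_cohort, file.path(out, "null"))

message(sprintf("cohort: %d genes x %d samples, %d hot / %d cold",
                nrow(cohort$expression), ncol(cohort$expression),
                sum(cohort$truth == "hot"), sum(cohort$truth == "cold")))
message(sprintf("events: %d (%.0f%% censored); responders: %d",
                sum(cohort$clinical$os_event),
                100 * mean(cohort$clinical$os_event == 0),
                sum(cohort$clinical$response == "CR/PR", na.rm = TRUE)))
message("written to ", out, " (expression.tsv, clinical.tsv, signatures.gmt, truth.tsv)")
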