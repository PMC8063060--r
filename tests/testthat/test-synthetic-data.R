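test_that("cohort generation is deterministic and internally consistent", {
  p <- small_params(seed = 11)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)

  expect_identical(colnames(a$expression), a$clinical$sample_id)
  expect_identical(colnames(a$expression), names(a$truth))
  expect_true(all(a$clinical$os_time > 0))
  expect_true(all(a$clinical$os_event %in% c(0, 1)))
  expect_true(all(unlist(a$signatures$sets) %in% rownames(a$expression)))
  expect_setequal(unique(a$truth), c("hot", "cold"))

  # a different seed changes the data
  expect_false(identical(a$expression, generate_cohort(small_params(seed = 12))$expression))
})

test_that("invalid parameters are rejected with the offending field named", {
  expect_error(cohort_params(hot_fraction = 1.2), "hot_fraction")
  expect_error(cohort_params(noise_sd = 0), "noise_sd")
  expect_error(cohort_params(n_samples = 0), "n_samples")
  expect_error(cohort_params(baseline_hazard = -1), "baseline_hazard")
  expect_error(cohort_params(n_genes = 50, n_signatures = 10,
                             genes_per_signature = 10),
               "genes_per_signature")
})

test_that("effect_size = 0 leaves signature genes null: t-test p-values uniform", {
  pvals <- vapply(1:200, function(seed) {
    co <- generate_cohort(cohort_params(n_samples = 30, n_genes = 40,
                                        n_signatures = 2, genes_per_signature = 5,
                                        effect_size = 0, seed = seed))
    m <- colMeans(co$expression[unlist(co$signatures$sets), ])
    t.test(m[co$truth == "hot"], m[co$truth == "cold"])$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("uncensored exponential survival matches the analytic median", {
  co <- generate_cohort(cohort_params(n_samples = 5000, n_genes = 10,
                                      n_signatures = 1, genes_per_signature = 2,
                                      censor_rate = 0, seed = 5))
  med_hot <- median(co$clinical$os_time[co$truth == "hot"])
  expect_lt(abs(med_hot - log(2) / 0.02) / (log(2) / 0.02), 0.10)
  # cold group carries twice the hazard
  med_cold <- median(co$clinical$os_time[co$truth == "cold"])
  expect_lt(abs(med_cold - log(2) / 0.04) / (log(2) / 0.04), 0.10)
})

test_that("censoring calibration hits the requested rate", {
  co <- generate_cohort(cohort_params(n_samples = 5000, n_genes = 10,
                                      n_signatures = 1, genes_per_signature = 2,
                                      censor_rate = 0.3, seed = 6))
  expect_lt(abs(mean(co$clinical$os_event == 0) - 0.3), 0.03)
})

test_that("null cohorts are null: Cox HR near 1 and calibrated group tests", {
  # HR estimate inside [0.6, 1.67] in >= 90% of replicates at n = 200
  inside <- vapply(1:100, function(seed) {
    co <- generate_null_cohort(cohort_params(n_samples = 200, n_genes = 10,
                                             n_signatures = 1,
                                             genes_per_signature = 2,
                                             seed = seed))
    hr <- cox_univariate(as.numeric(co$truth == "cold"), co$clinical$os_time,
                         co$clinical$os_event)$HR
    hr >= 0.6 && hr <= 1.67
  }, logical(1))
  expect_gte(mean(inside), 0.90)

  # log-rank on truth and chi-square on response reject at ~ the nominal 5%
  rej <- t(vapply(1:300, function(seed) {
    co <- generate_null_cohort(cohort_params(n_samples = 100, n_genes = 10,
                                             n_signatures = 1,
                                             genes_per_signature = 2,
                                             seed = 1000 + seed))
    lr <- logrank_test(co$truth, co$clinical$os_time, co$clinical$os_event)
    tab <- table(co$truth, co$clinical$response)
    chi <- chisq_contingency(matrix(tab, 2, 2)) |> suppressWarnings()
    c(lr = lr$p < 0.05, chi = chi$p < 0.05)
  }, logical(2)))
  expect_gt(mean(rej[, "lr"]), 0.02)
  expect_lt(mean(rej[, "lr"]), 0.09)
  expect_gt(mean(rej[, "chi"]), 0.02)
  expect_lt(mean(rej[, "chi"]), 0.09)
})

test_that("stronger expression effects never hurt downstream phenotype recovery", {
  mean_ari <- vapply(c(0.5, 1.5, 3), function(eff) {
    mean(vapply(1:20, function(seed) {
      co <- generate_cohort(small_params(seed = seed, effect_size = eff,
                                         censor_rate = 0.2))
      em <- ssgsea_scores(co$expression, co$signatures)
      cc <- consensus_cluster(t(em$scores),
                              consensus_params(k_range = 2:3, n_resamples = 20,
                                               seed = seed))
      adjusted_rand_index(cc$labels[["2"]], co$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= -0.02))
  expect_gt(mean_ari[3], 0.95)
})

test_that("cohort round-trips through its on-disk representation", {
  co <- generate_cohort(small_params(seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, co$expression, tolerance = 1e-12)
  cl <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(cl$os_time, co$clinical$os_time, tolerance = 1e-12)
  sets <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_identical(sets$sets, co$signatures$sets)
})
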