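test_that("univariate Cox estimates recover a known hazard ratio", {
  # two-group exponential survival, true HR = 2, no censoring
  inside <- vapply(1:100, function(seed) {
    set.seed(seed)
    grp <- rep(c(0, 1), each = 250)
    times <- rexp(500, rate = ifelse(grp == 1, 0.04, 0.02))
    hr <- cox_univariate(grp, times, rep(1, 500))$HR
    hr >= 1.7 && hr <= 2.35
  }, logical(1))
  expect_gte(mean(inside), 0.90)
})

test_that("Cox fits respect model symmetries and reject degenerate input", {
  set.seed(12)
  x <- rnorm(80)
  times <- rexp(80, exp(0.5 * x) * 0.05)
  ev <- rbinom(80, 1, 0.8)
  ev[1] <- 1
  f1 <- cox_univariate(x, times, ev)
  f2 <- cox_univariate(-x, times, ev)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
  expect_true(f1$lo95 < f1$HR && f1$HR < f1$hi95)

  expect_error(cox_univariate(rep(1, 80), times, ev), "constant")
  expect_error(cox_univariate(x, times, rep(0, 80)), "no events")
})

test_that("prognostic filter keeps true signals and stays calibrated under the null", {
  # empty input passes through
  co <- generate_cohort(small_params(seed = 13))
  out <- filter_prognostic(character(0), co$expression, co$clinical)
  expect_identical(out$genes, character(0))

  # null: kept fraction near the nominal p_max
  frac <- vapply(1:20, function(seed) {
    con <- generate_null_cohort(cohort_params(n_samples = 60, n_genes = 100,
                                              n_signatures = 2,
                                              genes_per_signature = 5,
                                              seed = 60 + seed))
    res <- filter_prognostic(rownames(con$expression), con$expression,
                             con$clinical, p_max = 0.05)
    length(res$genes) / nrow(con$expression)
  }, numeric(1))
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})

test_that("PC1 signatures have closed-form behavior on degenerate blocks", {
  # two perfectly correlated genes: PC1 proportional to the shared z-profile
  set.seed(14)
  v <- rnorm(10)
  expr <- rbind(g1 = v, g2 = 2 * v + 3, g3 = rnorm(10))
  colnames(expr) <- paste0("S", 1:10)
  pc1 <- pc1_signature(expr, c("g1", "g2"))
  z <- (v - mean(v)) / sd(v)
  expect_equal(unname(pc1 / sqrt(2)), z, tolerance = 1e-8)
  expect_gte(cor(pc1, z), 0)

  # duplicated gene row: degenerate but defined
  expr2 <- rbind(a = v, b = v)
  colnames(expr2) <- paste0("S", 1:10)
  pc2 <- pc1_signature(expr2, c("a", "b"))
  expect_equal(abs(cor(pc2, v)), 1, tolerance = 1e-10)

  # scaling one gene's raw values is absorbed by the z-scoring
  expr3 <- expr
  expr3["g1", ] <- expr3["g1", ] * 10
  expect_equal(pc1_signature(expr3, c("g1", "g2")), pc1, tolerance = 1e-10)

  expect_error(pc1_signature(expr, "g1"), "too small")
})

test_that("the signed TME score follows its defining arithmetic", {
  pc1 <- list(A = c(s1 = 1, s2 = 2), B = c(s1 = 0.5, s2 = 0.5))
  hr <- c(A = 1.8, B = 0.6)
  expect_equal(unname(tme_score(pc1, hr)), c(0.5, 1.5))

  # single protective cluster: score = -PC1
  expect_equal(unname(tme_score(pc1["B"], hr["B"])), c(-0.5, -0.5))

  # sign-flip linearity
  flipped <- lapply(pc1, function(v) -v)
  expect_equal(tme_score(flipped, hr), -tme_score(pc1, hr))
  expect_equal(tme_score(pc1, hr, orient = -1), -tme_score(pc1, hr))

  # invariance to cluster ordering
  expect_equal(tme_score(pc1[c("B", "A")], hr), tme_score(pc1, hr))

  expect_warning(tme_score(pc1, c(A = 1, B = 0.6)), "HR exactly 1")
  expect_error(tme_score(pc1, c(A = 2)), "hazard-ratio")
})

test_that("maximally selected log-rank dichotomization finds the survival gap", {
  # events concentrated at low scores, long censored times at high scores;
  # a 2-per-side floor leaves the cut between 2 and 3 as the only candidate
  # that the exhaustive evaluation can select
  score <- c(1, 2, 3, 4)
  times <- c(1, 2, 30, 32)
  events <- c(1, 1, 0, 0)
  d <- dichotomize_score(score, times, events, min_group_frac = 0.5,
                         method = "maxsel")
  expect_gte(d$cutpoint, 2)
  expect_lt(d$cutpoint, 3)
  expect_equal(as.character(d$groups), c("low", "low", "high", "high"))

  # larger cohort with a strong survival gap at the score midpoint
  set.seed(151)
  score_l <- 1:20
  times_l <- c(rexp(10, 0.5), rexp(10, 0.01))
  events_l <- c(rep(1, 10), rbinom(10, 1, 0.3))
  dl <- dichotomize_score(score_l, times_l, events_l)
  expect_gte(sum(dl$groups == "high"), 8)
  expect_gte(sum(dl$groups == "low"), 8)
  expect_gte(adjusted_rand_index(dl$groups, rep(c("a", "b"), each = 10)), 0.8)

  # rank-based candidates: monotone transforms give the same partition
  set.seed(15)
  s2 <- rnorm(40)
  t2 <- rexp(40, ifelse(s2 > 0, 0.02, 0.08))
  e2 <- rbinom(40, 1, 0.8); e2[1:2] <- 1
  d1 <- dichotomize_score(s2, t2, e2)
  d2 <- dichotomize_score(exp(s2), t2, e2)
  expect_identical(as.character(d1$groups), as.character(d2$groups))

  expect_error(dichotomize_score(rep(1, 10), rexp(10), rep(1, 10)),
               "degenerate")

  # median split balances the groups
  dm <- dichotomize_score(s2, t2, e2, method = "median")
  expect_equal(unname(abs(diff(table(dm$groups)))), 0)
})
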