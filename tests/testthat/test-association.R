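test_that("group comparison routes and computes the classical tests", {
  # exact Wilcoxon on disjoint small samples: p = 2 / C(6,3) = 0.1
  w <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                      force_method = "wilcoxon")
  expect_equal(w$p, 0.1)
  expect_identical(w$method, "wilcoxon")

  # three identical groups: Kruskal-Wallis H = 0, p = 1
  k <- compare_groups(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                      force_method = "kruskal_wallis")
  expect_equal(unname(k$statistic), 0)
  expect_equal(k$p, 1)

  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), "b")
  expect_error(compare_groups(1:6, rep(c("a", "b"), each = 3),
                              force_method = "anova"), "not match")
})

test_that("exact Wilcoxon p-values match full enumeration", {
  set.seed(19)
  for (i in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 2); y <- round(rnorm(n2, 0.5), 2)
    if (anyDuplicated(c(x, y))) next
    mine <- compare_groups(c(x, y), rep(c("a", "b"), c(n1, n2)),
                           force_method = "wilcoxon")$p
    expect_equal(mine, brute_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("the t-test route rejects at the nominal rate under the null", {
  rej <- vapply(1:500, function(seed) {
    set.seed(seed)
    compare_groups(rnorm(30), rep(c("a", "b"), each = 15),
                   force_method = "t")$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Shapiro-Wilk routing picks rank tests for skewed data", {
  set.seed(20)
  normal <- compare_groups(rnorm(40), rep(c("a", "b"), each = 20))
  expect_identical(normal$method, "t")
  skewed <- compare_groups(exp(rnorm(40, 0, 2)), rep(c("a", "b"), each = 20))
  expect_identical(skewed$method, "wilcoxon")
  three <- compare_groups(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_identical(three$method, "anova")
})

test_that("chi-square contingency test matches hand calculation and symmetries", {
  perfect <- matrix(c(10, 0, 0, 10), 2)
  res <- suppressWarnings(chisq_contingency(perfect))
  expect_equal(res$chi_square, 20)
  expect_equal(res$df, 1)

  # independence: table proportional to the outer product of its margins
  indep <- outer(c(10, 20), c(6, 4)) / 10
  expect_equal(suppressWarnings(chisq_contingency(indep))$chi_square, 0,
               tolerance = 1e-12)

  tab <- matrix(c(12, 5, 7, 9, 3, 8), 2)
  expect_equal(suppressWarnings(chisq_contingency(t(tab))$chi_square),
               suppressWarnings(chisq_contingency(tab)$chi_square),
               tolerance = 1e-12)

  expect_error(chisq_contingency(matrix(c(1, 2, 0, 0), 2)), "margin")
  expect_warning(chisq_contingency(matrix(c(3, 1, 2, 4), 2)), "below 5")
})

test_that("correlation measures distinguish linear from nonlinear dependence", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$coefficient, 1, tolerance = 1e-12)

  # quadratic: no linear correlation but clear distance correlation
  xs <- c(-4, -3, -2, -1, 1, 2, 3, 4)
  ys <- xs^2
  expect_equal(correlate(xs, ys)$coefficient, 0, tolerance = 1e-12)
  dc <- correlate(xs, ys, method = "distance")$coefficient
  expect_gt(dc, 0.3)
  expect_equal(dc, brute_dcor(xs, ys), tolerance = 1e-10)

  # independence: the (biased) empirical distance correlation is small and
  # shrinks with sample size
  set.seed(21)
  dcs50 <- vapply(1:100, function(i)
    correlate(rnorm(50), rnorm(50), method = "distance")$coefficient,
    numeric(1))
  dcs200 <- vapply(1:30, function(i)
    correlate(rnorm(200), rnorm(200), method = "distance")$coefficient,
    numeric(1))
  expect_lt(mean(dcs50), 0.3)
  expect_lt(mean(dcs200), mean(dcs50))

  expect_error(correlate(rep(1, 5), rnorm(5)), "non-constant")
})

test_that("over-representation analysis gives exact hypergeometric tails", {
  universe <- paste0("g", 1:10)
  sets <- gene_set_collection(list(hit_set = universe[1:5],
                                   other = universe[6:9]))
  res <- ora(universe[1:5], sets, universe)
  expect_equal(res$p[res$set == "hit_set"], 1 / choose(10, 5), tolerance = 1e-12)

  # empty hit list: all p = 1
  res0 <- ora(character(0), sets, universe)
  expect_true(all(res0$p == 1))

  expect_error(ora(c("g1", "nope"), sets, universe), "nope")

  # Monte-Carlo cross-check of the tail probability
  set.seed(22)
  big_univ <- paste0("u", 1:200)
  set_g <- big_univ[1:30]
  hits <- sample(big_univ, 25)
  ov <- length(intersect(set_g, hits))
  p_exact <- ora(hits, gene_set_collection(list(s = set_g)), big_univ)$p
  sim <- vapply(1:20000, function(i)
    sum(sample(200, 25) <= 30) >= ov, logical(1))
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(mean(sim) - p_exact), 3 * mc_sd + 1e-4)
})

test_that("score-response association detects a true link and rejects degenerate input", {
  ps <- vapply(1:10, function(seed) {
    co <- generate_cohort(small_params(seed = 70 + seed, n_samples = 100,
                                       response_logit_slope = 2))
    scored <- data.frame(
      tme_score = colMeans(co$expression[unlist(co$signatures$sets), ]),
      score_group = factor(ifelse(co$truth == "hot", "high", "low")))
    assoc <- suppressWarnings(
      score_response_association(scored, co$clinical$response))
    assoc$wilcoxon$p
  }, numeric(1))
  expect_lt(median(ps), 0.05)

  scored1 <- data.frame(tme_score = rnorm(10),
                        score_group = rep(c("high", "low"), 5))
  expect_error(score_response_association(scored1, rep("CR/PR", 10)),
               "2 response categories")
})
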