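test_that("PAM solves small instances exactly and handles edge cases", {
  d <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  res <- pam(d, 2)
  expect_equal(res$labels, c(1L, 1L, 2L, 2L))
  expect_equal(res$cost, brute_pam_cost(d, 2), tolerance = 1e-12)

  # k = n: every item its own medoid at zero cost
  res_n <- pam(d, 4)
  expect_equal(res_n$medoids, 1:4)
  expect_equal(res_n$cost, 0)

  # k = 1: the medoid minimizes the dissimilarity row sum
  set.seed(2)
  d5 <- as.matrix(dist(rnorm(7)))
  res1 <- pam(d5, 1)
  expect_equal(res1$medoids, unname(which.min(rowSums(d5))))

  expect_error(pam(matrix(c(0, 1, 2, 0), 2, 2), 1), "symmetric")
  expect_error(pam(-d, 2), "non-negative")
})

test_that("PAM cost matches exhaustive enumeration and the cluster package", {
  # BUILD+SWAP is a local search: it can never beat the exhaustive optimum
  # and reaches it on the overwhelming majority of small instances
  hit <- vapply(1:15, function(seed) {
    set.seed(seed)
    n <- sample(4:8, 1)
    k <- sample(1:(n - 1), 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    cost <- pam(d, k)$cost
    best <- brute_pam_cost(d, k)
    expect_gte(cost, best - 1e-10)
    abs(cost - best) < 1e-10
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  # independent implementation on larger instances: never worse
  for (seed in 1:10) {
    set.seed(100 + seed)
    n <- sample(20:60, 1)
    k <- sample(2:5, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    ref <- cluster::pam(stats::as.dist(d), k)$objective["swap"] * n
    expect_lte(pam(d, k)$cost, ref + 1e-8)
  }
})

test_that("consensus matrices are valid and exact when resampling is disabled", {
  set.seed(4)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
  rownames(x) <- paste0("i", 1:20)
  cc <- consensus_cluster(x, consensus_params(k_range = 2:3, n_resamples = 10,
                                              item_fraction = 1, seed = 1))
  for (k in c("2", "3")) {
    cons <- cc$consensus[[k]]
    expect_true(all(cons >= 0 & cons <= 1))
    expect_equal(cons, t(cons))
    expect_equal(unname(diag(cons)), rep(1, 20))
    # full-item resampling leaves no randomness: entries are exactly 0 or 1
    expect_true(all(cons %in% c(0, 1)))
  }
})

test_that("consensus clustering is equivariant under item permutation", {
  set.seed(5)
  x <- rbind(matrix(rnorm(24, 0), 12), matrix(rnorm(24, 6), 12))
  rownames(x) <- paste0("i", 1:24)
  p <- sample(24)
  cc1 <- consensus_cluster(x, consensus_params(k_range = 2:3, n_resamples = 30,
                                               item_fraction = 1, seed = 3))
  cc2 <- consensus_cluster(x[p, ], consensus_params(k_range = 2:3,
                                                    n_resamples = 30,
                                                    item_fraction = 1, seed = 3))
  expect_equal(cc2$consensus[["2"]], cc1$consensus[["2"]][p, p],
               tolerance = 1e-12)
  expect_equal(adjusted_rand_index(cc2$labels[["2"]], cc1$labels[["2"]][p]), 1)
})

test_that("well-separated blobs give sharp consensus and correct optimal k", {
  set.seed(6)
  blob <- function(n, mu) matrix(rnorm(n * 2, mu), n)
  x <- rbind(blob(15, 0), blob(15, 10))
  rownames(x) <- paste0("i", 1:30)
  truth <- rep(1:2, each = 15)
  cc <- consensus_cluster(x, consensus_params(k_range = 2:5, n_resamples = 50,
                                              seed = 2))
  cons <- cc$consensus[["2"]]
  within <- cons[truth == 1, truth == 1]
  across <- cons[truth == 1, truth == 2]
  expect_true(all(within[upper.tri(within)] == 1))
  expect_true(all(across == 0))
  expect_equal(cc$optimal_k, 2L)
  expect_equal(adjusted_rand_index(cc$labels[["2"]], truth), 1)
})

test_that("TME phenotype recovery holds at strong effect sizes", {
  ari <- vapply(1:10, function(seed) {
    co <- generate_cohort(small_params(seed = 30 + seed, effect_size = 3,
                                       noise_sd = 1))
    em <- ssgsea_scores(co$expression, co$signatures)
    cc <- consensus_cluster(t(em$scores),
                            consensus_params(k_range = 2:3, n_resamples = 30,
                                             seed = seed))
    adjusted_rand_index(cc$labels[["2"]], co$truth)
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})
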