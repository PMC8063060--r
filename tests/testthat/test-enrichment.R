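test_that("ssGSEA reproduces the hand-computed running sums", {
  expr <- matrix(c(4, 3, 2, 1), 4, 1,
                 dimnames = list(paste0("g", 1:4), "S1"))
  sets <- gene_set_collection(list(top = "g1", bottom = "g4"))
  sc <- ssgsea_scores(expr, sets, alpha = 0, min_overlap = 1)
  # running sum for {g1}: 1, 2/3, 1/3, 0 -> 2; mirrored for {g4}
  expect_equal(unname(sc$scores["top", "S1"]), 2.0)
  expect_equal(unname(sc$scores["bottom", "S1"]), -2.0)
  expect_false(sc$normalized)
})

test_that("ssGSEA matches the brute-force running-sum oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    ng <- sample(4:12, 1)
    ns <- sample(1:4, 1)
    expr <- random_expr(ng, ns, seed = seed)
    alpha <- sample(c(0, 0.25, 1), 1)
    set_genes <- sample(rownames(expr), sample(2:(ng - 1), 1))
    sets <- gene_set_collection(list(s = set_genes))
    mine <- ssgsea_scores(expr, sets, alpha = alpha)$scores["s", ]
    ref <- brute_ssgsea(expr, set_genes, alpha)
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
  }
})

test_that("alpha = 0 scores depend on ranks only", {
  expr <- random_expr(20, 5, seed = 3)
  sets <- gene_set_collection(list(a = rownames(expr)[1:5],
                                   b = rownames(expr)[8:15]))
  base <- ssgsea_scores(expr, sets, alpha = 0)$scores
  expr2 <- expr
  expr2[, 2] <- exp(expr2[, 2])          # strictly monotone transform
  expect_equal(ssgsea_scores(expr2, sets, alpha = 0)$scores, base,
               tolerance = 1e-12)
})

test_that("adding a gene absent from every set only shrinks the out-of-set step", {
  for (seed in 1:10) {
    expr <- random_expr(8, 2, seed = seed)
    set_genes <- rownames(expr)[1:3]
    sets <- gene_set_collection(list(s = set_genes))
    grown <- rbind(expr, z_extra = rnorm(2) - 10)
    rownames(grown)[9] <- "z_extra"
    mine <- ssgsea_scores(grown, sets, alpha = 0.25)$scores["s", ]
    ref <- brute_ssgsea(grown, set_genes, 0.25)
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
  }
})

test_that("degenerate gene-set inputs are rejected with informative errors", {
  expr <- random_expr(4, 3, seed = 1)
  all_genes <- gene_set_collection(list(s = rownames(expr)))
  expect_error(ssgsea_scores(expr, all_genes), "complement")
  missing_set <- gene_set_collection(list(s = c("nope1", "nope2", "g01")))
  expect_error(ssgsea_scores(expr, missing_set, min_overlap = 2), "nope1")
  expect_error(gene_set_collection(list(a = "g1", a = "g2")), "duplicate")
  expect_error(gene_set_collection(list(a = character(0))), "non-empty")
})

test_that("min-max normalization maps onto [0,1], preserves order, idempotent", {
  em <- structure(list(scores = matrix(c(0, 4, 2, 2), 2, 2,
                                       dimnames = list(c("a", "b"), c("s1", "s2"))),
                       normalized = FALSE, alpha = 0.25),
                  class = "enrichment_matrix")
  nm <- minmax_normalize(em)
  expect_equal(unname(nm$scores), matrix(c(0, 1, 0.5, 0.5), 2, 2))
  expect_true(nm$normalized)
  # idempotence and order preservation on random matrices
  for (seed in 1:5) {
    em$scores <- matrix(rnorm(12), 3, 4,
                        dimnames = list(letters[1:3], LETTERS[1:4]))
    n1 <- minmax_normalize(em)
    expect_equal(minmax_normalize(n1)$scores, n1$scores, tolerance = 1e-12)
    expect_identical(order(n1$scores), order(em$scores))
    expect_equal(range(n1$scores), c(0, 1))
  }
  em$scores <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(minmax_normalize(em), "degenerate")
})

test_that("ESTIMATE-style scores are additive and track the hot phenotype", {
  co <- generate_cohort(small_params(seed = 9, effect_size = 2,
                                     n_samples = 100))
  imm <- co$signatures$sets[[1]]
  str <- co$signatures$sets[[2]]
  es <- estimate_scores(co$expression, imm, str)
  expect_equal(es$estimate_score, es$immune_score + es$stromal_score,
               tolerance = 1e-12)
  # identical sets double the score
  es2 <- estimate_scores(co$expression, imm, imm)
  expect_equal(es2$estimate_score, 2 * es2$immune_score, tolerance = 1e-12)
  # hot samples score higher
  w <- wilcox.test(es$immune_score[co$truth == "hot"],
                   es$immune_score[co$truth == "cold"],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
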