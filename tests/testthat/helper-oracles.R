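# Independent reference implementations used to cross-check the package.
# These are deliberately written as plain, slow loops over the definitions.

# ssGSEA by direct accumulation of the running sum, one position at a time.
brute_ssgsea <- function(expr, set_genes, alpha) {
  genes <- rownames(expr)
  sapply(colnames(expr), function(s) {
    r <- rank(expr[, s], ties.method = "average")
    ord <- order(-r, genes, method = "radix")
    walk_genes <- genes[ord]
    n <- length(genes)
    inset <- walk_genes %in% set_genes
    m <- sum(inset)
    wsum <- sum(r[ord][inset]^alpha)
    running <- 0
    score <- 0
    for (i in seq_len(n)) {
      if (inset[i]) running <- running + r[ord][i]^alpha / wsum
      else running <- running - 1 / (n - m)
      score <- score + running
    }
    score
  })
}

# exact k-medoids by exhaustive enumeration of all medoid sets
brute_pam_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all group assignments
brute_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  all_sets <- combn(length(pooled), n1, simplify = FALSE)
  stats <- vapply(all_sets, function(idx) sum(rank(pooled)[idx]), numeric(1))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-9)
}

# distance correlation straight from the double-centering definition
brute_dcor <- function(x, y) {
  n <- length(x)
  A <- as.matrix(dist(x)); B <- as.matrix(dist(y))
  Ac <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  Bc <- B - outer(rowMeans(B), rep(1, n)) - outer(rep(1, n), colMeans(B)) + mean(B)
  v <- mean(Ac * Bc)
  vx <- mean(Ac^2); vy <- mean(Bc^2)
  sqrt(max(v, 0) / sqrt(vx * vy))
}

# small cohort settings reused by several suites
small_params <- function(seed, ...) {
  defaults <- list(n_samples = 60L, n_genes = 200L, n_signatures = 4L,
                   genes_per_signature = 10L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_params, args)
}

# random expression matrix with gene/sample names
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples),
         n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("S%02d", seq_len(n_samples))))
}
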