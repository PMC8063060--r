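#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, used throughout the package to compare
#' recovered cluster/group labels against latent phenotype truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a number in \[-1, 1\]; 1 for identical partitions, ~0 for random.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber it.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# scalar validators ---------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_proportion <- function(x, name, lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok)
    stop(sprintf("'%s' must be a single number in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"),
         call. = FALSE)
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  as.numeric(x)
}

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  as.numeric(x)
}
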