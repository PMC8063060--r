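#' PAM (k-medoids) clustering of a dissimilarity matrix
#'
#' Deterministic Partitioning Around Medoids: the BUILD phase greedily seeds
#' k medoids, then the SWAP phase exchanges a medoid for a non-medoid while
#' any single exchange lowers the total within-cluster dissimilarity. All ties
#' break toward the lowest index, so identical input gives identical output.
#'
#' @param dissimilarity symmetric non-negative numeric matrix with zero diagonal.
#' @param k number of clusters, `1 <= k <= nrow(dissimilarity)`.
#' @return list with `medoids` (sorted item indices), `labels` (1..k, item i
#'   assigned to its nearest medoid), and `cost` (total dissimilarity of items
#'   to their medoids).
#' @export
#' @examples
#' x <- c(0, 0.1, 10, 10.1)
#' d <- as.matrix(dist(x))
#' pam(d, 2)$labels  # 1 1 2 2
pam <- function(dissimilarity, k) {
  d <- dissimilarity
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("'dissimilarity' must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("'dissimilarity' must be finite and non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("'dissimilarity' must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("'dissimilarity' must have a zero diagonal", call. = FALSE)
  k <- check_count(k, "k")
  if (k > nrow(d)) stop("'k' cannot exceed the number of items", call. = FALSE)
  res <- .pam_cpp(d, k)
  res$labels <- as.integer(res$labels)
  res$medoids <- as.integer(res$medoids)
  res
}

#' Consensus-clustering parameters
#'
#' @param k_range integer vector of candidate cluster numbers, minimum >= 2.
#' @param n_resamples number of subsampled clustering runs (>= 2).
#' @param item_fraction fraction of items drawn (without replacement) per run,
#'   in (0, 1].
#' @param distance `"euclidean"` (rows of the data matrix) or
#'   `"one_minus_pearson"` (1 - Pearson correlation between rows).
#' @param seed integer seed for the resampling stream.
#' @return validated list of class `consensus_params`.
#' @export
consensus_params <- function(k_range = 2:4, n_resamples = 100L,
                             item_fraction = 0.8,
                             distance = c("euclidean", "one_minus_pearson"),
                             seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1L || min(k_range) < 2L)
    stop("'k_range' must contain integers >= 2", call. = FALSE)
  structure(list(
    k_range = k_range,
    n_resamples = check_count(n_resamples, "n_resamples", min = 2L),
    item_fraction = check_proportion(item_fraction, "item_fraction", open_hi = FALSE),
    distance = match.arg(distance),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "consensus_params")
}

#' Resampling consensus clustering with PAM
#'
#' For each resample, a fraction of the items is drawn without replacement and
#' PAM-clustered at each candidate k; the consensus matrix entry (i, j) is the
#' fraction of co-sampled runs in which i and j landed in the same cluster.
#' Final labels per k come from average-linkage hierarchical clustering of
#' 1 - consensus, cut at k. The optimal k is the smallest k with a crisp
#' consensus (see [optimal_k()]); consensus-CDF areas and delta areas are
#' recorded as diagnostics.
#'
#' @param data numeric items x features matrix (>= 4 items); items are what
#'   gets clustered (samples for TME phenotypes, genes for gene clusters).
#' @param params a [consensus_params()] object.
#' @return object of class `consensus_result`: list with `k_range`,
#'   `consensus` (named list of items x items matrices), `labels` (named list
#'   of integer vectors), `cdf_areas`, `delta_areas`, `optimal_k`, and
#'   `never_cosampled` (logical; TRUE when some pair was never co-sampled).
#' @export
consensus_cluster <- function(data, params = consensus_params()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric items x features matrix", call. = FALSE)
  n <- nrow(data)
  if (n < 4L) stop("consensus clustering needs >= 4 items", call. = FALSE)
  if (ncol(data) < 1L) stop("'data' needs >= 1 feature", call. = FALSE)
  if (!inherits(params, "consensus_params")) params <- do.call(consensus_params, params)
  if (max(params$k_range) >= n)
    stop("max of 'k_range' must be below the number of items", call. = FALSE)

  d_full <- switch(params$distance,
    euclidean = as.matrix(dist(data)),
    one_minus_pearson = {
      if (ncol(data) < 2L)
        stop("one_minus_pearson distance needs >= 2 features", call. = FALSE)
      dd <- 1 - cor(t(data))
      dd[dd < 0] <- 0          # numerical guard
      diag(dd) <- 0
      dd
    })

  m <- ceiling(params$item_fraction * n)
  ks <- params$k_range
  co_cluster <- lapply(ks, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(ks)
  co_sample <- matrix(0, n, n)

  with_seed(params$seed, {
    for (b in seq_len(params$n_resamples)) {
      idx <- sort(sample.int(n, m))
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      d_sub <- d_full[idx, idx, drop = FALSE]
      for (k in ks) {
        lab <- .pam_cpp(d_sub, k)$labels
        same <- outer(lab, lab, "==")
        kk <- as.character(k)
        co_cluster[[kk]][idx, idx] <- co_cluster[[kk]][idx, idx] + same
      }
    }
  })

  never <- co_sample == 0
  diag(never) <- FALSE
  if (any(rowSums(never) == n - 1L))
    warning("some items were never co-sampled with any other item; ",
            "their consensus rows are zero-filled")

  item_names <- rownames(data)
  consensus <- lapply(co_cluster, function(cc) {
    cons <- ifelse(co_sample > 0, cc / pmax(co_sample, 1), 0)
    cons[co_sample == 0] <- 0
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(item_names, item_names)
    cons
  })
  labels <- lapply(seq_along(ks), function(i) {
    hc <- hclust(as.dist(1 - consensus[[i]]), method = "average")
    lab <- cutree(hc, k = ks[i])
    if (!is.null(item_names)) names(lab) <- item_names
    lab
  })
  names(labels) <- as.character(ks)

  areas <- vapply(consensus, .consensus_cdf_area, numeric(1))
  res <- structure(list(k_range = ks, consensus = consensus, labels = labels,
                        cdf_areas = areas, delta_areas = NULL, optimal_k = NULL,
                        never_cosampled = any(never), params = params),
                   class = "consensus_result")
  if (length(ks) >= 2L) {
    k_opt <- optimal_k(res)
    res$delta_areas <- attr(k_opt, "delta_areas")
    res$pac <- attr(k_opt, "pac")
    res$optimal_k <- as.integer(k_opt)
  } else {
    res$delta_areas <- setNames(areas, as.character(ks))
    res$pac <- NULL
    res$optimal_k <- ks[1]
  }
  res
}

# Area under the empirical CDF of the off-diagonal consensus values over [0,1].
.consensus_cdf_area <- function(cons) {
  x <- sort(cons[upper.tri(cons)])
  n <- length(x)
  xs <- c(x, 1)
  f <- seq_len(n) / n
  sum(diff(xs) * f)
}

#' Select the optimal number of clusters from consensus matrices
#'
#' Selection uses the proportion of ambiguous clustering (PAC): the fraction
#' of off-diagonal consensus values that fall strictly inside
#' `(bounds[1], bounds[2])` — pairs whose co-clustering is neither clearly
#' "never" nor clearly "always". The optimal k is the smallest k whose PAC is
#' at most `pac_max`; when no k clusters crisply, the floor (smallest
#' candidate k) is returned. The classical consensus-CDF areas and relative
#' delta areas are still computed and attached as attributes — they are
#' informative diagnostics, but splitting even a perfectly crisp cluster
#' inflates the CDF area of the next k under resampling, so a delta-area
#' threshold systematically overcounts clusters; PAC does not (see the
#' package vignette).
#'
#' @param result a `consensus_result` with at least two k values.
#' @param pac_max largest PAC accepted as a crisp clustering (default 0.1,
#'   i.e. at most 10% ambiguous pairs).
#' @param bounds lower/upper consensus bounds defining "ambiguous"
#'   (default 0.1 and 0.9).
#' @return the selected k (integer), with attributes `pac` (per-k PAC) and
#'   `delta_areas` (per-k relative CDF-area increase).
#' @export
optimal_k <- function(result, pac_max = 0.1, bounds = c(0.1, 0.9)) {
  if (!inherits(result, "consensus_result"))
    stop("'result' must be a consensus_result", call. = FALSE)
  ks <- result$k_range
  if (length(ks) < 2L) stop("'k_range' must contain >= 2 values", call. = FALSE)
  pac <- vapply(result$consensus, function(cons) {
    x <- cons[upper.tri(cons)]
    mean(x > bounds[1] & x < bounds[2])
  }, numeric(1))
  names(pac) <- as.character(ks)
  a <- result$cdf_areas
  delta <- c(a[1], diff(a) / a[-length(a)])
  names(delta) <- as.character(ks)
  ok <- which(pac <= pac_max)
  k_opt <- if (length(ok)) ks[min(ok)] else ks[1]
  attr(k_opt, "pac") <- pac
  attr(k_opt, "delta_areas") <- delta
  k_opt
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d items, k in {%s}, optimal k = %d\n",
              nrow(x$consensus[[1]]), paste(x$k_range, collapse = ","),
              as.integer(x$optimal_k)))
  invisible(x)
}
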