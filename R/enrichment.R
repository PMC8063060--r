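#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids. Set names must be
#'   unique and every set non-empty; duplicate genes within a set are dropped,
#'   keeping first occurrence.
#' @param source free-text provenance (e.g. a GMT path).
#' @return object of class `gene_set_collection` with elements `sets`, `source`.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list of gene id vectors", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty", call. = FALSE)
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d genes total (%s)\n",
              length(x$sets), length(unique(unlist(x$sets))),
              if (nzchar(x$source)) x$source else "no source"))
  invisible(x)
}

.check_expression <- function(expr, min_genes = 2L, min_samples = 2L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression must carry gene row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression", call. = FALSE)
  if (!all(is.finite(expr))) stop("expression contains non-finite values", call. = FALSE)
  if (nrow(expr) < min_genes || ncol(expr) < min_samples)
    stop(sprintf("expression needs >= %d genes and >= %d samples", min_genes, min_samples),
         call. = FALSE)
  invisible(expr)
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample independently, genes are ranked by decreasing expression
#' (ties by average rank, then stably by gene id) and a weighted
#' Kolmogorov-Smirnov-like running sum is accumulated down the list: at an
#' in-set gene it increases by `rank^alpha / sum(in-set rank^alpha)`, at an
#' out-of-set gene it decreases by `1/(N - m)` (N genes in the matrix, m in
#' the set). The ssGSEA score of the set in that sample is the sum of the
#' running-sum values over all N positions. Scores are returned unnormalized;
#' see [minmax_normalize()].
#'
#' @param expr numeric genes x samples matrix, log scale, with dimnames.
#' @param sets a [gene_set_collection()].
#' @param alpha non-negative rank-weighting exponent; 0.25 is the published
#'   ssGSEA weight, 0 gives a purely rank-position statistic.
#' @param min_overlap minimum number of set genes that must be present in
#'   `expr` (default 2).
#' @return object of class `enrichment_matrix`: list with `scores` (sets x
#'   samples numeric matrix), `normalized` (FALSE here) and `alpha`.
#' @export
#' @examples
#' expr <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(paste0("g", 1:4), "S1"))
#' sets <- gene_set_collection(list(top = "g1", bottom = "g4"))
#' ssgsea_scores(expr, sets, alpha = 0, min_overlap = 1)$scores  # 2 and -2
ssgsea_scores <- function(expr, sets, alpha = 0.25, min_overlap = 2L) {
  .check_expression(expr, min_samples = 1L)
  if (!inherits(sets, "gene_set_collection"))
    stop("'sets' must be a gene_set_collection", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("'alpha' must be a single non-negative number", call. = FALSE)
  min_overlap <- check_count(min_overlap, "min_overlap")

  genes <- rownames(expr)
  n_genes <- length(genes)
  member <- lapply(sets$sets, function(s) {
    present <- s[s %in% genes]
    if (length(present) < min_overlap) {
      missing <- s[!s %in% genes]
      stop(sprintf("gene set overlap below min_overlap=%d (%d of %d genes present); missing: %s",
                   min_overlap, length(present), length(s),
                   paste(head(missing, 10L), collapse = ", ")), call. = FALSE)
    }
    if (length(present) >= n_genes)
      stop("gene set covers every gene in the matrix: complement is empty", call. = FALSE)
    match(present, genes)
  })

  scores <- matrix(NA_real_, length(member), ncol(expr),
                   dimnames = list(names(sets$sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")       # high expression -> high rank
    ord <- order(-r, genes, method = "radix")           # walk in decreasing expression
    r_walk <- r[ord]
    in_walk <- matrix(FALSE, n_genes, length(member))
    pos <- match(seq_len(n_genes), ord)                 # gene index -> walk position
    for (k in seq_along(member)) in_walk[pos[member[[k]]], k] <- TRUE
    w <- r_walk^alpha
    for (k in seq_along(member)) {
      inset <- in_walk[, k]
      m <- sum(inset)
      step <- ifelse(inset, w / sum(w[inset]), -1 / (n_genes - m))
      scores[k, j] <- sum(cumsum(step))
    }
  }
  structure(list(scores = scores, normalized = FALSE, alpha = alpha),
            class = "enrichment_matrix")
}

#' Min-max normalize an enrichment matrix
#'
#' Maps all scores affinely onto \[0, 1\] using the global minimum and maximum
#' over every set and sample, preserving order. Idempotent: a second call is
#' the identity on the values.
#'
#' @param scores an `enrichment_matrix` from [ssgsea_scores()].
#' @return an `enrichment_matrix` with `normalized = TRUE`.
#' @export
minmax_normalize <- function(scores) {
  if (!inherits(scores, "enrichment_matrix"))
    stop("'scores' must be an enrichment_matrix", call. = FALSE)
  rng <- range(scores$scores)
  if (rng[1] == rng[2])
    stop("degenerate range: all enrichment scores identical", call. = FALSE)
  scores$scores <- (scores$scores - rng[1]) / (rng[2] - rng[1])
  scores$normalized <- TRUE
  scores
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d sets x %d samples (alpha=%g, %snormalized)\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$normalized) "" else "un"))
  invisible(x)
}

#' ESTIMATE-style immune, stromal and combined infiltration scores
#'
#' Scores an immune and a stromal signature per sample with unnormalized
#' ssGSEA and combines them additively: the combined score proxies the total
#' non-tumor (immune + stromal) content of each sample.
#'
#' @param expr numeric genes x samples matrix with dimnames.
#' @param immune_set,stromal_set character vectors of gene ids.
#' @param alpha ssGSEA exponent, see [ssgsea_scores()].
#' @param min_overlap minimum set overlap with `expr`.
#' @return data.frame with `sample_id`, `immune_score`, `stromal_score`,
#'   `estimate_score` (= immune + stromal).
#' @export
estimate_scores <- function(expr, immune_set, stromal_set, alpha = 0.25,
                            min_overlap = 2L) {
  sets <- gene_set_collection(list(immune = immune_set, stromal = stromal_set),
                              source = "estimate_scores input")
  em <- ssgsea_scores(expr, sets, alpha = alpha, min_overlap = min_overlap)
  data.frame(sample_id = colnames(em$scores),
             immune_score = em$scores["immune", ],
             stromal_score = em$scores["stromal", ],
             estimate_score = em$scores["immune", ] + em$scores["stromal", ],
             row.names = NULL, stringsAsFactors = FALSE)
}
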