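#' Normality-routed group comparison
#'
#' Compares a numeric variable across groups, choosing the test the way the
#' workflow does throughout: Shapiro-Wilk normality per group at alpha = 0.05;
#' when every group looks normal, Student's t (two groups, pooled variance)
#' or one-way ANOVA (more), otherwise Wilcoxon rank-sum or Kruskal-Wallis.
#' The Wilcoxon p-value is exact for combined n <= 20 without ties, and uses
#' the tie-corrected normal approximation otherwise.
#'
#' @param values numeric vector.
#' @param labels group labels aligned with `values`; >= 2 groups, each with
#'   n >= 2 (n >= 3 when the routing has to run Shapiro-Wilk).
#' @param force_method optional: `"t"`, `"wilcoxon"`, `"anova"` or
#'   `"kruskal_wallis"` to skip the routing.
#' @return list of class `group_comparison` with `method`, `statistic`, `p`,
#'   and `summaries` (per-group n/mean/median/sd).
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
#'                force_method = "wilcoxon")$p  # 0.1
compare_groups <- function(values, labels, force_method = NULL) {
  if (!is.numeric(values) || length(values) != length(labels))
    stop("'values' must be numeric and aligned with 'labels'", call. = FALSE)
  labels <- factor(labels)
  labels <- droplevels(labels)
  g <- split(values, labels)
  if (length(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  ns <- lengths(g)
  small <- names(ns)[ns < 2L]
  if (length(small))
    stop("group(s) below minimum size (n >= 2): ", paste(small, collapse = ", "),
         call. = FALSE)

  two <- length(g) == 2L
  if (is.null(force_method)) {
    small3 <- names(ns)[ns < 3L]
    if (length(small3))
      stop("normality routing needs n >= 3 per group; too small: ",
           paste(small3, collapse = ", "), call. = FALSE)
    normal <- vapply(g, function(v) {
      if (length(unique(v)) < 2L) return(FALSE)   # constant: not normal-like
      shapiro.test(v)$p.value >= 0.05
    }, logical(1))
    method <- if (all(normal)) (if (two) "t" else "anova")
              else (if (two) "wilcoxon" else "kruskal_wallis")
  } else {
    method <- match.arg(force_method, c("t", "wilcoxon", "anova", "kruskal_wallis"))
    if (two != (method %in% c("t", "wilcoxon")))
      stop("'", method, "' does not match the number of groups", call. = FALSE)
  }

  res <- switch(method,
    t = {
      tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    },
    wilcoxon = {
      n_comb <- sum(ns)
      ties <- anyDuplicated(values) > 0
      wt <- suppressWarnings(
        wilcox.test(g[[1]], g[[2]], exact = n_comb <= 20 && !ties,
                    correct = !(n_comb <= 20 && !ties)))
      list(statistic = unname(wt$statistic), p = wt$p.value)
    },
    anova = {
      av <- summary(aov(values ~ labels))[[1]]
      list(statistic = av[["F value"]][1], p = av[["Pr(>F)"]][1])
    },
    kruskal_wallis = {
      kw <- kruskal.test(values, labels)
      list(statistic = unname(kw$statistic), p = kw$p.value)
    })
  if (is.na(res$p)) res$p <- 1  # e.g. all groups identical in kruskal/anova

  summaries <- data.frame(group = names(g), n = as.integer(ns),
                          mean = vapply(g, mean, numeric(1)),
                          median = vapply(g, stats::median, numeric(1)),
                          sd = vapply(g, sd, numeric(1)),
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(method = method, statistic = res$statistic, p = res$p,
                 summaries = summaries), class = "group_comparison")
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (rows - 1)(cols - 1); a warning is emitted when any expected count
#' falls below 5.
#'
#' @param table numeric matrix of non-negative counts with positive margins.
#' @return list with `chi_square`, `df`, `p`, `expected`.
#' @export
#' @examples
#' chisq_contingency(matrix(c(10, 0, 0, 10), 2))$chi_square  # 20
chisq_contingency <- function(table) {
  if (!is.matrix(table) || !is.numeric(table) || any(table < 0) ||
      any(!is.finite(table)))
    stop("'table' must be a numeric matrix of non-negative counts", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("'table' must be at least 2 x 2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: every row and column needs a positive total", call. = FALSE)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count(s) below 5; chi-square approximation is rough")
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Pearson or distance correlation
#'
#' Pearson correlation with the usual t-based two-sided p-value, or the
#' (double-centered) distance correlation of Szekely et al., which lies in
#' \[0, 1\] and vanishes only under independence (no p-value is computed for
#' the distance variant).
#'
#' @param x,y numeric vectors of equal length (>= 3 for pearson, >= 4 for
#'   distance); neither constant.
#' @param method `"pearson"` or `"distance"`.
#' @return list with `coefficient` and (pearson only) `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "distance")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("'x' and 'y' must be numeric vectors of equal length", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("degenerate input: 'x' and 'y' must be non-constant", call. = FALSE)
  if (method == "pearson") {
    if (length(x) < 3L) stop("pearson correlation needs n >= 3", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson")
    list(coefficient = unname(ct$estimate), p = ct$p.value)
  } else {
    if (length(x) < 4L) stop("distance correlation needs n >= 4", call. = FALSE)
    list(coefficient = .distance_correlation(x, y))
  }
}

.distance_correlation <- function(x, y) {
  dc <- function(v) {
    d <- abs(outer(v, v, "-"))
    d - rowMeans(d) - rep(colMeans(d), each = length(v)) + mean(d)
  }
  a <- dc(x); b <- dc(y)
  dcov2 <- mean(a * b)
  dvar_x <- mean(a * a)
  dvar_y <- mean(b * b)
  if (dvar_x <= 0 || dvar_y <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvar_x * dvar_y))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail test P(X >= overlap) of a hit list against
#' each gene set, restricted to a stated gene universe, with BH adjustment
#' across sets. Sets without any gene in the universe are dropped with a
#' warning.
#'
#' @param hits character vector of significant genes; must lie inside
#'   `universe`.
#' @param sets a [gene_set_collection()].
#' @param universe character vector of all testable genes.
#' @return data.frame with `set`, `set_size` (in universe), `overlap`,
#'   `expected`, `p`, `adj_p`, ordered as in `sets`.
#' @export
ora <- function(hits, sets, universe) {
  if (!inherits(sets, "gene_set_collection"))
    stop("'sets' must be a gene_set_collection", call. = FALSE)
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, universe)
  if (length(outside))
    stop("hit gene(s) outside the universe: ",
         paste(head(outside, 10L), collapse = ", "), call. = FALSE)
  n_univ <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(sets$sets), function(nm) {
    set_u <- intersect(sets$sets[[nm]], universe)
    if (length(set_u) == 0L) {
      warning("set '", nm, "' has no gene in the universe; dropped")
      return(NULL)
    }
    ov <- length(intersect(set_u, hits))
    data.frame(set = nm, set_size = length(set_u), overlap = ov,
               expected = n_hits * length(set_u) / n_univ,
               p = phyper(ov - 1, length(set_u), n_univ - length(set_u),
                          n_hits, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0), adj_p = numeric(0)))
  res$adj_p <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Associate the TME score with immunotherapy response
#'
#' Two complementary views of the score/response relationship: a Wilcoxon
#' rank-sum comparison of the continuous TME score between responders (CR/PR)
#' and non-responders (SD/PD), and a chi-square test of the dichotomized
#' score group against response.
#'
#' @param scored data.frame with per-sample `tme_score` and `score_group`
#'   columns (as produced by the pipeline).
#' @param response character/factor response labels aligned with `scored`;
#'   `NA`s are dropped. Needs >= 2 categories with >= 2 samples each.
#' @return list with `wilcoxon` (a `group_comparison`), `chisq` (list), and
#'   `counts` (score_group x response table).
#' @export
score_response_association <- function(scored, response) {
  if (!is.data.frame(scored) ||
      !all(c("tme_score", "score_group") %in% names(scored)))
    stop("'scored' needs columns tme_score and score_group", call. = FALSE)
  if (length(response) != nrow(scored))
    stop("'response' must align with 'scored'", call. = FALSE)
  keep <- !is.na(response)
  response <- factor(response[keep])
  response <- droplevels(response)
  scored <- scored[keep, , drop = FALSE]
  if (nlevels(response) < 2L)
    stop("need >= 2 response categories", call. = FALSE)
  if (any(table(response) < 2L))
    stop("each response category needs >= 2 samples", call. = FALSE)
  wil <- compare_groups(scored$tme_score, response,
                        force_method = if (nlevels(response) == 2L) "wilcoxon"
                                       else "kruskal_wallis")
  counts <- table(score_group = scored$score_group, response = response)
  chi <- chisq_contingency(matrix(counts, nrow(counts), ncol(counts),
                                  dimnames = dimnames(counts)))
  list(wilcoxon = wil, chisq = chi, counts = counts)
}
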