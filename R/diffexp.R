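#' Moderated two-group differential expression
#'
#' Gene-wise two-group comparison on log-scale expression with empirical-Bayes
#' variance moderation. Each gene's pooled residual variance `s_g^2` (on
#' `d_g = n1 + n2 - 2` df) is shrunk toward a prior variance `s0^2` with prior
#' df `d0`, as `s2_post = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`, where
#' `(d0, s0^2)` are estimated by matching the moments of the log residual
#' variances to a scaled inverse-chi-square prior (trigamma inversion). The
#' moderated t is `logFC / (sqrt(s2_post) * sqrt(1/n1 + 1/n2))` on `d0 + d_g`
#' df, with two-sided p-values. logFC is the mean of the first group minus
#' the mean of the second (first level of `factor(groups)`).
#'
#' @param expr numeric genes x samples matrix with dimnames.
#' @param groups binary label vector (length = samples); each group
#'   needs at least 2 samples.
#' @param prior_df optional override of the estimated prior df: `0` disables
#'   moderation (ordinary pooled t), `Inf` forces a single common variance.
#' @return data.frame of class `de_result` with one row per gene: `gene`,
#'   `logFC`, `t`, `p_value`, `adj_p` (BH), `mean_expr`, `flagged` (TRUE for
#'   all-constant genes whose variance comes entirely from the prior).
#'   Attributes: `d0` (prior df), `s0_sq` (prior variance), `reference`
#'   (which group is the logFC baseline).
#' @export
moderated_de <- function(expr, groups, prior_df = NULL) {
  .check_expression(expr)
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must contain exactly 2 distinct labels", call. = FALSE)
  if (length(groups) != ncol(expr))
    stop("'groups' length must equal the number of samples", call. = FALSE)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2L)
    stop(sprintf("each group needs >= 2 samples (got %d and %d)", n1, n2),
         call. = FALSE)

  g1 <- groups == levels(groups)[1]
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, !g1, drop = FALSE])
  logfc <- m1 - m2
  rss <- rowSums((expr[, g1, drop = FALSE] - m1)^2) +
    rowSums((expr[, !g1, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- rss / dg

  if (is.null(prior_df)) {
    fit <- .fit_variance_prior(s2, dg)
    d0 <- fit$d0
    s0_sq <- fit$s0_sq
  } else {
    if (!is.numeric(prior_df) || length(prior_df) != 1L || prior_df < 0)
      stop("'prior_df' must be a single non-negative number (may be Inf)",
           call. = FALSE)
    d0 <- prior_df
    s0_sq <- if (d0 > 0) .fit_variance_prior(s2, dg)$s0_sq else 0
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + dg * s2) / (d0 + dg)
  flagged <- s2 == 0
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, 0)
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[se == 0] <- 1

  res <- data.frame(gene = rownames(expr), logFC = logfc, t = tstat,
                    p_value = p, adj_p = bh_adjust(p),
                    mean_expr = rowMeans(expr), flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  attr(res, "reference") <- sprintf("logFC = mean(%s) - mean(%s)",
                                    levels(groups)[1], levels(groups)[2])
  class(res) <- c("de_result", "data.frame")
  res
}

# Moment-matching fit of a scaled inverse-chi-square prior to gene variances:
# model s2 ~ s0_sq * F(dg, d0); on the log scale,
#   E[e] = log(s0_sq) with e = log(s2) - digamma(dg/2) + log(dg/2)
#          + digamma(d0/2) - log(d0/2)
#   Var[log s2] = trigamma(dg/2) + trigamma(d0/2).
# Zero variances are excluded from the fit; no positive solution => d0 = Inf.
.fit_variance_prior <- function(s2, dg) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L) return(list(d0 = Inf, s0_sq = max(mean(s2), .Machine$double.eps)))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- var(z) - trigamma(dg / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(x) = y, y > 0.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control: sort p ascending, take running minima of
#' `m * p_(j) / j` from the largest rank down, cap at 1, return in input
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of FDR-adjusted values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.03 0.03
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("'p' must be numeric with all values in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Filter differentially expressed genes
#'
#' Keeps genes that clear both the FDR and fold-change thresholds with strict
#' inequalities: `adj_p < adj_p_max` and `|logFC| > min_abs_lfc`. Input order
#' is preserved.
#'
#' @param res a `de_result` from [moderated_de()].
#' @param adj_p_max FDR threshold (default 0.01).
#' @param min_abs_lfc absolute log2 fold-change threshold (default 1).
#' @return character vector of gene ids.
#' @export
filter_degs <- function(res, adj_p_max = 0.01, min_abs_lfc = 1) {
  if (!inherits(res, "de_result")) stop("'res' must be a de_result", call. = FALSE)
  check_positive(adj_p_max, "adj_p_max")
  check_positive(min_abs_lfc, "min_abs_lfc")
  res$gene[res$adj_p < adj_p_max & abs(res$logFC) > min_abs_lfc]
}
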