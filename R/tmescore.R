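#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit of a single covariate (Breslow tie handling,
#' Newton-Raphson via the `survival` engine) with Wald inference. Monotone
#' likelihood (perfect risk separation) is detected, the coefficient capped at
#' |beta| = 15, and the fit flagged with a warning.
#'
#' @param x numeric per-sample covariate (non-constant).
#' @param os_time positive survival/censoring times.
#' @param os_event event indicators in \{0, 1\}; at least one event.
#' @return data.frame of class `cox_fit` with `term`, `beta`, `HR`, `se`,
#'   `lo95`, `hi95`, `p`, `monotone` (TRUE when the likelihood was monotone).
#' @export
cox_univariate <- function(x, os_time, os_event) {
  .check_survival(os_time, os_event)
  if (!is.numeric(x) || length(x) != length(os_time))
    stop("'x' must be numeric and aligned with the survival data", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate covariate: 'x' is constant", call. = FALSE)
  .cox_fit(data.frame(x = x), os_time, os_event, terms = "x")
}

#' Multivariate Cox proportional-hazards fit
#'
#' Joint partial-likelihood fit of several covariates (Breslow ties) with
#' per-covariate hazard ratios, 95% confidence intervals and Wald p-values —
#' the model behind a forest plot of the TME score adjusted for clinical
#' covariates.
#'
#' @param covariates data.frame of numeric/factor covariates, one row per
#'   sample; the design matrix must be full rank.
#' @param os_time,os_event as in [cox_univariate()].
#' @return `cox_fit` data.frame with one row per model term.
#' @export
cox_multivariate <- function(covariates, os_time, os_event) {
  .check_survival(os_time, os_event)
  if (!is.data.frame(covariates) || ncol(covariates) < 1L)
    stop("'covariates' must be a data.frame with >= 1 column", call. = FALSE)
  if (nrow(covariates) != length(os_time))
    stop("'covariates' rows must align with the survival data", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = covariates)
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    stop("collinear design: column(s) ", paste(dropped, collapse = ", "),
         " are linearly dependent", call. = FALSE)
  }
  .cox_fit(covariates, os_time, os_event, terms = colnames(covariates))
}

.check_survival <- function(os_time, os_event) {
  if (!is.numeric(os_time) || any(!is.finite(os_time)) || any(os_time <= 0))
    stop("'os_time' must be positive and finite", call. = FALSE)
  if (length(os_event) != length(os_time) || !all(os_event %in% c(0, 1)))
    stop("'os_event' must be 0/1 and aligned with 'os_time'", call. = FALSE)
  if (sum(os_event) == 0)
    stop("no events: survival model carries no information", call. = FALSE)
  invisible(TRUE)
}

.cox_fit <- function(covariates, os_time, os_event, terms) {
  dat <- cbind(data.frame(.time = os_time, .event = os_event), covariates)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (monotone || any(abs(beta) > 15)) {
    monotone <- TRUE
    warning("monotone partial likelihood (perfect separation); ",
            "coefficient(s) capped at |beta| = 15")
    beta <- pmin(pmax(beta, -15), 15)
  }
  res <- data.frame(term = names(beta), beta = beta, HR = exp(beta), se = se,
                    lo95 = exp(beta - 1.96 * se), hi95 = exp(beta + 1.96 * se),
                    p = 2 * pnorm(-abs(beta / se)), monotone = monotone,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("cox_fit", "data.frame")
  res
}

#' Keep genes whose expression is prognostic
#'
#' Fits a univariate Cox model per gene and keeps genes with Wald p strictly
#' below `p_max`, retaining the fits so downstream code can read each gene's
#' hazard-ratio direction. Genes absent from the matrix or with constant
#' expression are dropped with a warning.
#'
#' @param degs character vector of candidate gene ids (may be empty).
#' @param expr numeric genes x samples matrix.
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event` covering
#'   the expression samples.
#' @param p_max Wald p-value threshold in (0, 1), default 0.05.
#' @return list with `genes` (character, input order) and `fits` (data.frame
#'   with one row per tested gene: gene, beta, HR, p, kept).
#' @export
filter_prognostic <- function(degs, expr, clinical, p_max = 0.05) {
  check_proportion(p_max, "p_max")
  degs <- as.character(degs)
  if (length(degs) == 0L)
    return(list(genes = character(0),
                fits = data.frame(gene = character(0), beta = numeric(0),
                                  HR = numeric(0), p = numeric(0),
                                  kept = logical(0))))
  cl <- .align_clinical(expr, clinical)
  expr <- expr[, cl$sample_id, drop = FALSE]
  missing <- setdiff(degs, rownames(expr))
  if (length(missing)) {
    warning(length(missing), " candidate gene(s) absent from the matrix; dropped")
    degs <- setdiff(degs, missing)
  }
  rows <- lapply(degs, function(g) {
    x <- expr[g, ]
    if (length(unique(x)) < 2L) {
      warning("gene ", g, " has constant expression; dropped")
      return(NULL)
    }
    f <- cox_univariate(x, cl$os_time, cl$os_event)
    data.frame(gene = g, beta = f$beta, HR = f$HR, p = f$p,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  if (is.null(fits))
    return(list(genes = character(0),
                fits = data.frame(gene = character(0), beta = numeric(0),
                                  HR = numeric(0), p = numeric(0),
                                  kept = logical(0))))
  fits$kept <- fits$p < p_max
  list(genes = fits$gene[fits$kept], fits = fits)
}

.align_clinical <- function(expr, clinical) {
  if (!is.data.frame(clinical) ||
      !all(c("sample_id", "os_time", "os_event") %in% names(clinical)))
    stop("'clinical' needs columns sample_id, os_time, os_event", call. = FALSE)
  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) < 3L)
    stop("fewer than 3 samples shared between expression and clinical data",
         call. = FALSE)
  dropped <- ncol(expr) - length(common)
  if (dropped > 0)
    message(dropped, " expression sample(s) without clinical data dropped")
  clinical[match(common, clinical$sample_id), , drop = FALSE]
}

#' First-principal-component signature score
#'
#' Z-scores each signature gene across samples, then projects the samples on
#' the leading principal component of the standardized gene-by-sample block.
#' The sign of PC1 is fixed so that it correlates positively with the mean
#' z-score of the signature genes (PCA signs are otherwise arbitrary).
#'
#' @param expr numeric genes x samples matrix (>= 3 samples).
#' @param genes character vector of signature genes; >= 2 must be present.
#' @return named numeric vector of per-sample PC1 scores.
#' @export
pc1_signature <- function(expr, genes) {
  .check_expression(expr, min_samples = 3L)
  genes <- intersect(as.character(genes), rownames(expr))
  if (length(genes) < 2L)
    stop("signature too small: fewer than 2 genes overlap the matrix", call. = FALSE)
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from the signature")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2L)
      stop("signature too small after dropping zero-variance genes", call. = FALSE)
  }
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  sv <- svd(z)
  pc1 <- sv$v[, 1] * sv$d[1]
  names(pc1) <- colnames(expr)
  ref <- colMeans(z)
  if (sd(pc1) > 0 && sd(ref) > 0 && cor(pc1, ref) < 0) pc1 <- -pc1
  pc1
}

#' Signed TME score from gene-cluster signatures
#'
#' Combines per-gene-cluster PC1 signature scores into one per-sample score:
#' the sum of PC1 over clusters whose expression carries a hazard ratio above
#' 1 (risk clusters) minus the sum over clusters with hazard ratio below 1
#' (protective clusters). A cluster with HR exactly 1 carries no prognostic
#' direction; it is placed on the protective side with a warning. `orient`
#' multiplies the final score by +1/-1, allowing the pipeline to fix the
#' global sign convention (by default the pipeline orients high score =
#' good prognosis).
#'
#' @param pc1_by_cluster named list (or data.frame) of per-sample PC1 vectors,
#'   one element per gene cluster; equal lengths and sample order.
#' @param hr_by_cluster named numeric vector of cluster-level hazard ratios;
#'   names must cover the clusters.
#' @param orient +1 or -1 global sign (default +1 = the raw formula).
#' @return named numeric vector of per-sample TME scores.
#' @export
#' @examples
#' tme_score(list(A = c(1, 2), B = c(0.5, 0.5)), c(A = 1.8, B = 0.6))
#' # A added (HR > 1), B subtracted: 0.5 1.5
tme_score <- function(pc1_by_cluster, hr_by_cluster, orient = 1) {
  if (is.data.frame(pc1_by_cluster)) pc1_by_cluster <- as.list(pc1_by_cluster)
  if (!is.list(pc1_by_cluster) || length(pc1_by_cluster) < 1L)
    stop("'pc1_by_cluster' must be a non-empty named list", call. = FALSE)
  cl_names <- names(pc1_by_cluster)
  if (is.null(cl_names) || !all(cl_names %in% names(hr_by_cluster)))
    stop("every cluster needs a hazard-ratio direction in 'hr_by_cluster'",
         call. = FALSE)
  if (!orient %in% c(1, -1)) stop("'orient' must be +1 or -1", call. = FALSE)
  lens <- lengths(pc1_by_cluster)
  if (length(unique(lens)) != 1L)
    stop("PC1 vectors must have equal length", call. = FALSE)
  hr <- hr_by_cluster[cl_names]
  if (any(hr <= 0)) stop("hazard ratios must be positive", call. = FALSE)
  if (any(hr == 1))
    warning("cluster(s) with HR exactly 1 assigned to the protective sum")
  score <- numeric(lens[1])
  for (i in seq_along(pc1_by_cluster))
    score <- score + ifelse(hr[i] > 1, 1, -1) * pc1_by_cluster[[i]]
  nm <- names(pc1_by_cluster[[1]])
  setNames(orient * score, nm)
}

#' Dichotomize a prognostic score by maximally selected log-rank statistics
#'
#' Evaluates the two-group log-rank chi-square statistic at every candidate
#' cut between consecutive distinct score values that leaves at least
#' `min_group_frac` of the samples on each side, and places the cutpoint at
#' the candidate maximizing the absolute standardized statistic (ties go to
#' the lowest cut). Candidates are rank-based, so any strictly monotone
#' transform of the scores yields the same partition. A median split is
#' available as a simple alternative.
#'
#' @param score numeric per-sample score with >= 2 distinct values.
#' @param os_time,os_event survival outcome, aligned with `score`.
#' @param min_group_frac minimum fraction of samples per side, in (0, 0.5\];
#'   default 0.1.
#' @param method `"maxsel"` (maximally selected log-rank, default) or
#'   `"median"`.
#' @return list with `cutpoint` (score value; samples with score > cutpoint
#'   are "high"), `groups` (factor "high"/"low"), `statistic` (log-rank
#'   chi-square at the cut; NA for median split).
#' @export
dichotomize_score <- function(score, os_time, os_event, min_group_frac = 0.1,
                              method = c("maxsel", "median")) {
  method <- match.arg(method)
  .check_survival(os_time, os_event)
  if (length(score) != length(os_time))
    stop("'score' must align with the survival data", call. = FALSE)
  if (length(unique(score)) < 2L)
    stop("degenerate score: all values identical", call. = FALSE)
  check_proportion(min_group_frac, "min_group_frac", lo = 0, hi = 0.5,
                   open_hi = FALSE)
  n <- length(score)
  if (method == "median") {
    cut <- stats::median(score)
    groups <- factor(ifelse(score > cut, "high", "low"), levels = c("low", "high"))
    if (nlevels(droplevels(groups)) < 2L)
      stop("median split leaves one group empty", call. = FALSE)
    return(list(cutpoint = cut, groups = groups, statistic = NA_real_))
  }
  v <- sort(unique(score))
  min_n <- ceiling(min_group_frac * n)
  cand <- v[-length(v)]
  cand <- cand[vapply(cand, function(cut) {
    hi <- sum(score > cut)
    hi >= min_n && (n - hi) >= min_n
  }, logical(1))]
  if (length(cand) == 0L)
    stop("no candidate cut leaves both groups above 'min_group_frac'",
         call. = FALSE)
  stats_at <- vapply(cand, function(cut) {
    grp <- score > cut
    sd_fit <- survival::survdiff(survival::Surv(os_time, os_event) ~ grp)
    sd_fit$chisq
  }, numeric(1))
  best <- which.max(stats_at)  # ties -> first = lowest cut
  cut <- cand[best]
  list(cutpoint = cut,
       groups = factor(ifelse(score > cut, "high", "low"), levels = c("low", "high")),
       statistic = stats_at[best])
}
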