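#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end TME workflow with the package
#' defaults: ssGSEA exponent 0.25, TME phenotypes fixed at k = 2 for the
#' differential-expression contrast (the diagnostics still report the
#' delta-area optimal k), the published consensus-clustering defaults
#' (100 resamples at 80% item fraction), DEG thresholds adjusted p < 0.01 and
#' |logFC| > 1, prognostic Cox filter p < 0.05, and a median split of the TME
#' score. The maximally selected log-rank cut is available via
#' `dichotomize_method = "maxsel"`, but it is not the pipeline default: the
#' prognostic gene filter has already consulted the same survival data, so the
#' score carries survival-aligned noise within phenotype groups and a
#' survival-maximizing cut systematically overfits it (see the package
#' vignette). `score_orientation` `"high_good"` flips the raw score sign,
#' when needed, so that a high TME score marks good prognosis; `"formula"`
#' keeps the raw signed-sum convention.
#'
#' @param alpha,normalize,min_overlap enrichment stage; see [ssgsea_scores()].
#' @param tme_k number of TME phenotypes used for the DE contrast.
#' @param consensus_k_range,n_resamples,item_fraction consensus stage; the
#'   TME stage uses euclidean distance on enrichment scores, the gene stage
#'   1 - Pearson on standardized expression.
#' @param gene_k_range candidate k for the gene clusters (selected by
#'   [optimal_k()]).
#' @param adj_p_max,min_abs_lfc DEG thresholds; see [filter_degs()].
#' @param cox_p_max prognostic filter threshold; see [filter_prognostic()].
#' @param min_group_frac,dichotomize_method see [dichotomize_score()].
#' @param score_orientation `"high_good"` (default) or `"formula"`.
#' @param seed integer master seed for the resampling stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.25, normalize = FALSE, min_overlap = 2L,
                            tme_k = 2L, consensus_k_range = 2:4,
                            n_resamples = 100L, item_fraction = 0.8,
                            gene_k_range = 2:4, adj_p_max = 0.01,
                            min_abs_lfc = 1, cox_p_max = 0.05,
                            min_group_frac = 0.1,
                            dichotomize_method = c("median", "maxsel"),
                            score_orientation = c("high_good", "formula"),
                            seed = 1L) {
  structure(list(
    alpha = alpha, normalize = isTRUE(normalize),
    min_overlap = check_count(min_overlap, "min_overlap"),
    tme_k = check_count(tme_k, "tme_k", min = 2L),
    consensus_k_range = sort(unique(as.integer(consensus_k_range))),
    n_resamples = check_count(n_resamples, "n_resamples", min = 2L),
    item_fraction = check_proportion(item_fraction, "item_fraction",
                                     open_hi = FALSE),
    gene_k_range = sort(unique(as.integer(gene_k_range))),
    adj_p_max = check_positive(adj_p_max, "adj_p_max"),
    min_abs_lfc = check_positive(min_abs_lfc, "min_abs_lfc"),
    cox_p_max = check_proportion(cox_p_max, "cox_p_max"),
    min_group_frac = check_proportion(min_group_frac, "min_group_frac",
                                      lo = 0, hi = 0.5, open_hi = FALSE),
    dichotomize_method = match.arg(dichotomize_method),
    score_orientation = match.arg(score_orientation),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "pipeline_config")
}

#' Run the TME workflow in memory
#'
#' Executes the full chain on already-loaded inputs: ssGSEA enrichment of the
#' immune signatures, consensus PAM clustering of samples into TME
#' phenotypes, moderated differential expression between the two phenotypes,
#' univariate-Cox prognostic filtering of the DEGs, consensus clustering of
#' the prognostic genes, per-cluster PC1 signature scores, the signed TME
#' score, maximally selected log-rank dichotomization, and the survival and
#' response association reports. Deterministic given the config seed.
#'
#' @param expr numeric genes x samples matrix.
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event` and
#'   optionally `age` and `response`.
#' @param signatures a [gene_set_collection()] of immune-cell signatures.
#' @param config a [pipeline_config()].
#' @return list of class `tme_analysis` with elements `enrichment`,
#'   `tme_consensus`, `tme_clusters`, `de`, `degs`, `prognostic`,
#'   `gene_consensus`, `gene_clusters`, `pc1`, `cluster_hr`, `orientation`,
#'   `scored` (per-sample table with pc1 columns, `tme_score`, `score_group`),
#'   `cutpoint`, `survival_report`, `association_report`, `config`.
#' @export
analyze_cohort <- function(expr, clinical, signatures,
                           config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cl <- stage("align", .align_clinical(expr, clinical))
  expr <- expr[, cl$sample_id, drop = FALSE]

  # 1. single-sample enrichment of the immune signatures
  enr <- stage("enrichment", {
    em <- ssgsea_scores(expr, signatures, alpha = config$alpha,
                        min_overlap = config$min_overlap)
    if (config$normalize) em <- minmax_normalize(em)
    em
  })

  # 2. consensus clustering of samples into TME phenotypes
  tme_cons <- stage("tme_clusters", {
    kr <- sort(unique(c(config$consensus_k_range, config$tme_k)))
    consensus_cluster(t(enr$scores),
                      consensus_params(k_range = kr,
                                       n_resamples = config$n_resamples,
                                       item_fraction = config$item_fraction,
                                       distance = "euclidean",
                                       seed = config$seed + 1L))
  })
  tme_labels <- stage("tme_clusters", {
    lab <- tme_cons$labels[[as.character(config$tme_k)]]
    # orient names so cluster 1 = immune-high (highest mean enrichment)
    mean_enr <- colMeans(enr$scores)
    ord <- order(-vapply(split(mean_enr, lab), mean, numeric(1)))
    factor(match(lab, ord), levels = seq_along(ord))
  })

  # 3. moderated DE between the two TME phenotypes
  if (config$tme_k != 2L)
    stop("the differential-expression contrast requires tme_k = 2", call. = FALSE)
  de <- stage("diffexp", moderated_de(expr, tme_labels))
  degs <- stage("diffexp", filter_degs(de, adj_p_max = config$adj_p_max,
                                       min_abs_lfc = config$min_abs_lfc))

  # 4. prognostic filter
  prog <- stage("prognostic_filter",
                filter_prognostic(degs, expr, cl, p_max = config$cox_p_max))
  if (length(prog$genes) < 4L)
    stop("pipeline stage 'prognostic_filter' failed: fewer than 4 prognostic ",
         "genes; gene clustering is not possible", call. = FALSE)

  # 5. consensus clustering of prognostic genes
  gene_cons <- stage("gene_clusters", {
    z <- expr[prog$genes, , drop = FALSE]
    z <- (z - rowMeans(z)) / apply(z, 1, sd)
    kr <- config$gene_k_range[config$gene_k_range < length(prog$genes)]
    if (length(kr) < 2L) kr <- 2:min(3L, length(prog$genes) - 1L)
    consensus_cluster(z, consensus_params(k_range = kr,
                                          n_resamples = config$n_resamples,
                                          item_fraction = config$item_fraction,
                                          distance = "one_minus_pearson",
                                          seed = config$seed + 2L))
  })
  gene_clusters <- stage("gene_clusters", {
    lab <- gene_cons$labels[[as.character(gene_cons$optimal_k)]]
    # cluster 1 = genes most positively correlated with overall immune enrichment
    imm <- colMeans(enr$scores)
    gcor <- apply(expr[prog$genes, , drop = FALSE], 1, function(v)
      if (sd(v) > 0) cor(v, imm) else 0)
    ord <- order(-vapply(split(gcor, lab), mean, numeric(1)))
    lab2 <- match(lab, ord)
    names(lab2) <- names(lab)
    split(names(lab2), paste0("gene_cluster_", lab2))
  })

  # 6. PC1 signature per gene cluster
  pc1 <- stage("pc1_signatures", {
    out <- lapply(gene_clusters, function(gs) {
      if (length(gs) >= 2L) pc1_signature(expr, gs)
      else {  # single-gene cluster: its z-score profile is the signature
        v <- expr[gs, ]
        setNames(as.numeric(scale(v)), colnames(expr))
      }
    })
    out
  })

  # 7. cluster-level prognostic direction and the signed TME score
  hr <- stage("tme_score", vapply(pc1, function(v)
    cox_univariate(v, cl$os_time, cl$os_event)$HR, numeric(1)))
  names(hr) <- names(pc1)
  raw_score <- stage("tme_score", tme_score(pc1, hr))
  orientation <- 1
  if (config$score_orientation == "high_good") {
    beta <- stage("tme_score",
                  cox_univariate(raw_score, cl$os_time, cl$os_event)$beta)
    if (beta > 0) orientation <- -1
  }
  score <- orientation * raw_score

  # 8. dichotomization
  dich <- stage("dichotomize",
                dichotomize_score(score, cl$os_time, cl$os_event,
                                  min_group_frac = config$min_group_frac,
                                  method = config$dichotomize_method))

  scored <- data.frame(sample_id = cl$sample_id,
                       as.data.frame(pc1, check.names = FALSE),
                       tme_score = unname(score),
                       score_group = dich$groups,
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)

  # 9. survival and response association reports
  surv_rep <- stage("survival", {
    km <- lapply(split(seq_len(nrow(cl)), dich$groups), function(i)
      km_estimate(cl$os_time[i], cl$os_event[i]))
    lr <- logrank_test(dich$groups, cl$os_time, cl$os_event)
    covars <- data.frame(tme_score_high = as.integer(dich$groups == "high"))
    if ("age" %in% names(cl)) covars$age <- cl$age
    cox <- cox_multivariate(covars, cl$os_time, cl$os_event)
    tau <- max(cl$os_time)
    rmean <- vapply(km, km_restricted_mean, numeric(1), tau = tau)
    list(km = km, logrank = lr, cox = cox, restricted_mean = rmean)
  })
  assoc_rep <- NULL
  if ("response" %in% names(cl) && sum(!is.na(cl$response)) >= 4L &&
      length(unique(stats::na.omit(cl$response))) >= 2L) {
    assoc_rep <- stage("association",
                       score_response_association(scored, cl$response))
  }

  structure(list(enrichment = enr, tme_consensus = tme_cons,
                 tme_clusters = setNames(tme_labels, cl$sample_id),
                 de = de, degs = degs, prognostic = prog,
                 gene_consensus = gene_cons, gene_clusters = gene_clusters,
                 pc1 = pc1, cluster_hr = hr, orientation = orientation,
                 scored = scored, cutpoint = dich$cutpoint,
                 dichotomy_statistic = dich$statistic,
                 survival_report = surv_rep, association_report = assoc_rep,
                 clinical = cl, config = config),
            class = "tme_analysis")
}

#' Run the full pipeline from files to an artifact bundle
#'
#' Reads the expression matrix, clinical table and signature GMT named in
#' `paths`, runs [analyze_cohort()], and writes nine stage outputs plus a
#' provenance manifest (config, seed, package version, per-file MD5
#' checksums) into `paths$output_dir`. Reruns with the same config are
#' byte-identical. Samples present in the expression matrix but absent from
#' the clinical table are dropped with a message.
#'
#' @param paths named list with `expression`, `clinical`, `signatures`
#'   (input files) and `output_dir`.
#' @param config a [pipeline_config()].
#' @return the `tme_analysis` object, invisibly, with the manifest path in
#'   attribute `manifest`.
#' @export
run_pipeline <- function(paths, config = pipeline_config()) {
  need <- c("expression", "clinical", "signatures", "output_dir")
  if (!all(need %in% names(paths)))
    stop("'paths' needs elements: ", paste(need, collapse = ", "), call. = FALSE)
  expr <- read_expression(paths$expression)
  clinical <- read_clinical(paths$clinical)
  signatures <- read_gmt(paths$signatures)
  res <- analyze_cohort(expr, clinical, signatures, config)

  out <- paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out, x)

  write_matrix_tsv(res$enrichment$scores, f("01_enrichment.tsv"),
                   id_column = "gene_set")
  write.table(data.frame(sample_id = names(res$tme_clusters),
                         tme_cluster = as.integer(res$tme_clusters)),
              f("02_tme_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$de[, c("gene", "logFC", "t", "p_value", "adj_p")],
              f("03_differential_expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$prognostic$fits, f("04_prognostic_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gc_df <- data.frame(
    gene = unlist(res$gene_clusters, use.names = FALSE),
    gene_cluster = rep(names(res$gene_clusters), lengths(res$gene_clusters)))
  write.table(gc_df, f("05_gene_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pc1_mat <- do.call(cbind, res$pc1)
  write_matrix_tsv(pc1_mat, f("06_pc1_signatures.tsv"), id_column = "sample_id")
  write.table(res$scored[, c("sample_id", "tme_score")], f("07_tme_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(res$scored[, c("sample_id", "score_group")],
                    cutpoint = res$cutpoint),
              f("08_score_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  reports <- list(
    logrank = res$survival_report$logrank,
    cox = res$survival_report$cox,
    restricted_mean_by_group = as.list(res$survival_report$restricted_mean),
    cluster_hr = as.list(res$cluster_hr),
    orientation = res$orientation,
    cutpoint = res$cutpoint,
    optimal_k_tme = res$tme_consensus$optimal_k,
    optimal_k_genes = res$gene_consensus$optimal_k,
    n_degs = length(res$degs),
    n_prognostic_genes = length(res$prognostic$genes),
    association = if (is.null(res$association_report)) NULL else list(
      wilcoxon_p = res$association_report$wilcoxon$p,
      chisq_p = res$association_report$chisq$p,
      counts = as.data.frame(res$association_report$counts)))
  jsonlite::write_json(reports, f("09_reports.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  stage_files <- c("01_enrichment.tsv", "02_tme_clusters.tsv",
                   "03_differential_expression.tsv", "04_prognostic_genes.tsv",
                   "05_gene_clusters.tsv", "06_pc1_signatures.tsv",
                   "07_tme_scores.tsv", "08_score_groups.tsv",
                   "09_reports.json")
  manifest <- list(
    package = "tmeprofiler",
    version = as.character(utils::packageVersion("tmeprofiler")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    inputs = list(expression = paths$expression, clinical = paths$clinical,
                  signatures = paths$signatures),
    checksums = as.list(tools::md5sum(vapply(stage_files, f, character(1)))))
  names(manifest$checksums) <- stage_files
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  attr(res, "manifest") <- f("manifest.json")
  invisible(res)
}

#' @export
print.tme_analysis <- function(x, ...) {
  cat("TME analysis\n")
  cat(sprintf("  samples: %d, DEGs: %d, prognostic genes: %d\n",
              nrow(x$scored), length(x$degs), length(x$prognostic$genes)))
  cat(sprintf("  gene clusters: %d (optimal k), orientation: %+d\n",
              length(x$gene_clusters), x$orientation))
  cat(sprintf("  score cutpoint: %.4g; log-rank chi-square %.3g (p = %.3g)\n",
              x$cutpoint, x$survival_report$logrank$chi_square,
              x$survival_report$logrank$p))
  invisible(x)
}
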