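#' Read a gene-expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene ids are collapsed by keeping the row with the highest mean
#' expression (a warning reports how many were dropped). Any non-numeric or
#' missing cell aborts with its row/column coordinates.
#'
#' @param path path to a tab-separated file.
#' @return numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L)
    stop("malformed expression file: need a gene-id column plus >= 1 sample",
         call. = FALSE)
  if (nrow(raw) == 0L) stop("empty expression file: ", path, call. = FALSE)
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d, column %d (gene %s, sample %s)",
                 bad[1, 1] + 1L, bad[1, 2] + 1L, gene_ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- gene_ids
  if (anyDuplicated(gene_ids)) {
    means <- rowMeans(num)
    ord <- order(-means)                      # highest-mean rows win
    keep <- ord[!duplicated(gene_ids[ord])]
    warning(length(gene_ids) - length(keep),
            " duplicate gene id row(s) collapsed, keeping the higher-mean row")
    num <- num[sort(keep), , drop = FALSE]
  }
  num
}

#' Write an expression (or any named) matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param id_column header for the first (row-name) column.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene ids. Duplicate genes within a set are kept once (first occurrence);
#' duplicate set names abort.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()] with `source = path`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT format error at line ", short[1],
         ": need name, description and >= 1 gene", call. = FALSE)
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets, source = path)
}

#' Write a gene-set collection as GMT
#'
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional named character vector of per-set
#'   descriptions; defaults to the collection source.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!inherits(sets, "gene_set_collection"))
    stop("'sets' must be a gene_set_collection", call. = FALSE)
  desc <- if (is.null(descriptions))
    setNames(rep(if (nzchar(sets$source)) sets$source else "na",
                 length(sets$sets)), names(sets$sets))
  else descriptions
  lines <- vapply(names(sets$sets), function(nm)
    paste(c(nm, desc[[nm]], sets$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes `expression.tsv` (genes x samples), `clinical.tsv` (one row per
#' sample, `NA` for missing values), `signatures.gmt` and `truth.tsv` into
#' `dir`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop("'cohort' must be a synthetic_cohort", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  write.table(data.frame(sample_id = names(cohort$truth),
                         phenotype = unname(cohort$truth)),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a clinical table from TSV
#'
#' @param path TSV with at least `sample_id`, `os_time`, `os_event` columns;
#'   "NA" marks missing values.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cl <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = "NA", quote = "")
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cl
}

#' Write a consensus-clustering result to disk
#'
#' Per-k consensus matrices and final labels as TSV, plus a JSON report of
#' the CDF areas, delta areas and the selected k.
#'
#' @param result a `consensus_result`.
#' @param dir output directory (created if needed).
#' @export
write_consensus_result <- function(result, dir) {
  if (!inherits(result, "consensus_result"))
    stop("'result' must be a consensus_result", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(result$consensus)) {
    cons <- result$consensus[[k]]
    if (is.null(rownames(cons)))
      dimnames(cons) <- list(paste0("item", seq_len(nrow(cons))),
                             paste0("item", seq_len(ncol(cons))))
    write_matrix_tsv(cons, file.path(dir, sprintf("consensus_k%s.tsv", k)),
                     id_column = "item")
    lab <- result$labels[[k]]
    write.table(data.frame(item = if (is.null(names(lab)))
                             paste0("item", seq_along(lab)) else names(lab),
                           cluster = unname(lab)),
                file.path(dir, sprintf("labels_k%s.tsv", k)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(k_range = result$k_range, cdf_areas = unname(result$cdf_areas),
         delta_areas = unname(result$delta_areas),
         pac = unname(result$pac), optimal_k = result$optimal_k),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
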