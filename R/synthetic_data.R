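#' Parameters for a synthetic TME cohort
#'
#' Bundles and validates the knobs of the synthetic-cohort generator. The
#' defaults describe the study conditions the package is exercised under: a
#' cohort of 120 tumors with two latent immune phenotypes ("hot"/"cold"),
#' 28 immune-cell signatures of 25 genes each inside a 1000-gene background,
#' a 3 log2-unit signature shift in hot tumors, exponential overall survival
#' with a twofold excess hazard in cold tumors, 30% censoring, and
#' immunotherapy-response odds that increase with the hot phenotype.
#'
#' @param n_samples number of tumors.
#' @param n_genes number of genes in the expression matrix.
#' @param n_signatures number of immune-cell signature gene sets.
#' @param genes_per_signature genes per signature; signatures are disjoint and
#'   `n_signatures * genes_per_signature` must not exceed `n_genes`.
#' @param hot_fraction fraction of samples with the immune-hot phenotype, in (0,1).
#' @param effect_size mean log2 expression shift added to signature genes in
#'   hot samples. 0 gives a null cohort.
#' @param noise_sd per-gene, per-sample log2 noise standard deviation (> 0).
#' @param baseline_hazard exponential event hazard of the hot group, events per
#'   time unit (months by convention).
#' @param hazard_ratio_cold_vs_hot multiplicative hazard of cold vs hot (> 0).
#' @param censor_rate target overall fraction of censored samples, in \[0,1).
#' @param response_logit_slope increase in log-odds of objective response
#'   (CR/PR) for hot vs cold samples.
#' @param response_fraction fraction of samples carrying a response label
#'   (emulating the subset treated with immunotherapy); the rest are `NA`.
#' @param seed single integer; the one seed from which every random draw in the
#'   generator derives.
#' @return an object of class `cohort_params` (a validated named list).
#' @export
cohort_params <- function(n_samples = 120L, n_genes = 1000L, n_signatures = 28L,
                          genes_per_signature = 25L, hot_fraction = 0.5,
                          effect_size = 3, noise_sd = 1, baseline_hazard = 0.02,
                          hazard_ratio_cold_vs_hot = 2, censor_rate = 0.3,
                          response_logit_slope = 2, response_fraction = 1,
                          seed = 1L) {
  p <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_genes = check_count(n_genes, "n_genes"),
    n_signatures = check_count(n_signatures, "n_signatures"),
    genes_per_signature = check_count(genes_per_signature, "genes_per_signature"),
    hot_fraction = check_proportion(hot_fraction, "hot_fraction"),
    effect_size = check_number(effect_size, "effect_size"),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    baseline_hazard = check_positive(baseline_hazard, "baseline_hazard"),
    hazard_ratio_cold_vs_hot = check_positive(hazard_ratio_cold_vs_hot,
                                              "hazard_ratio_cold_vs_hot"),
    censor_rate = check_proportion(censor_rate, "censor_rate", open_lo = FALSE),
    response_logit_slope = check_number(response_logit_slope, "response_logit_slope"),
    response_fraction = check_proportion(response_fraction, "response_fraction",
                                         open_lo = FALSE, open_hi = FALSE),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (p$genes_per_signature * p$n_signatures > p$n_genes)
    stop("'genes_per_signature' x 'n_signatures' must not exceed 'n_genes'",
         call. = FALSE)
  structure(p, class = "cohort_params")
}

#' Generate a synthetic cohort with two latent immune phenotypes
#'
#' Draws a log2-scale expression matrix with gene-wise baselines, shifts the
#' signature genes of immune-hot samples upward by `effect_size`, simulates
#' exponential overall survival with a `hazard_ratio_cold_vs_hot`-fold hazard
#' in cold samples, applies independent uniform censoring calibrated so that
#' the expected censored fraction equals `censor_rate`, and assigns
#' immunotherapy-response labels (CR/PR vs SD/PD) whose log-odds increase by
#' `response_logit_slope` in hot samples. Byte-identical output for identical
#' parameters (including the seed); the caller's RNG state is untouched.
#'
#' @param params a [cohort_params()] object (or arguments coercible to one via
#'   `cohort_params(...)` when a plain list is given).
#' @return an object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{expression}{numeric matrix, genes x samples, log2 scale.}
#'     \item{signatures}{a `gene_set_collection` of the signature gene sets.}
#'     \item{clinical}{data.frame with `sample_id`, `os_time`, `os_event`,
#'       `age`, `response`.}
#'     \item{truth}{named character vector of latent phenotypes, "hot"/"cold".}
#'     \item{params}{the parameters used.}
#'   }
#' @seealso [generate_null_cohort()], [write_cohort()]
#' @export
#' @examples
#' co <- generate_cohort(cohort_params(n_samples = 20, n_genes = 60,
#'                                     n_signatures = 3, genes_per_signature = 5,
#'                                     seed = 7))
#' dim(co$expression)
#' table(co$truth)
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  with_seed(params$seed, {
    n <- params$n_samples
    g <- params$n_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    sample_ids <- sprintf("S%03d", seq_len(n))

    # latent phenotype: fixed count, random placement
    n_hot <- max(1L, min(n - 1L, round(params$hot_fraction * n)))
    phenotype <- rep("cold", n)
    phenotype[sample.int(n, n_hot)] <- "hot"
    names(phenotype) <- sample_ids

    # disjoint signatures over the leading genes
    sig_gene_idx <- seq_len(params$n_signatures * params$genes_per_signature)
    sets <- split(gene_ids[sig_gene_idx],
                  rep(seq_len(params$n_signatures), each = params$genes_per_signature))
    names(sets) <- sprintf("TIIC_%02d", seq_len(params$n_signatures))
    signatures <- gene_set_collection(sets, source = "synthetic immune-cell signatures")

    # expression: per-gene baseline + iid noise; signature block shifted in hot
    baseline <- rnorm(g, mean = 6, sd = 2)
    expr <- matrix(rnorm(g * n, mean = 0, sd = params$noise_sd), g, n,
                   dimnames = list(gene_ids, sample_ids))
    expr <- expr + baseline
    hot <- phenotype == "hot"
    expr[sig_gene_idx, hot] <- expr[sig_gene_idx, hot] + params$effect_size

    # survival: exponential event times, uniform censoring hitting censor_rate
    rate <- ifelse(hot, params$baseline_hazard,
                   params$baseline_hazard * params$hazard_ratio_cold_vs_hot)
    t_event <- rexp(n, rate = rate)
    if (params$censor_rate > 0) {
      u_max <- .calibrate_uniform_censoring(params$censor_rate,
                                            rates = c(params$baseline_hazard,
                                                      params$baseline_hazard *
                                                        params$hazard_ratio_cold_vs_hot),
                                            weights = c(mean(hot), 1 - mean(hot)))
      t_cens <- runif(n, min = 0, max = u_max)
      os_time <- pmin(t_event, t_cens)
      os_event <- as.integer(t_event <= t_cens)
    } else {
      os_time <- t_event
      os_event <- rep(1L, n)
    }

    # response: logistic in the latent phenotype, labels on a subset
    base_logit <- qlogis(0.25)  # cold-group objective-response rate
    p_resp <- plogis(base_logit + params$response_logit_slope * as.numeric(hot))
    response <- ifelse(rbinom(n, 1L, p_resp) == 1L, "CR/PR", "SD/PD")
    n_lab <- round(params$response_fraction * n)
    if (n_lab < n) response[sample.int(n, n - n_lab)] <- NA_character_

    age <- pmin(85, pmax(25, round(rnorm(n, 52, 12))))

    clinical <- data.frame(sample_id = sample_ids, os_time = os_time,
                           os_event = os_event, age = age, response = response,
                           stringsAsFactors = FALSE)
    structure(list(expression = expr, signatures = signatures,
                   clinical = clinical, truth = phenotype, params = params),
              class = "synthetic_cohort")
  })
}

#' Generate a null cohort (no phenotype signal)
#'
#' Identical to [generate_cohort()] but with `effect_size = 0`,
#' `hazard_ratio_cold_vs_hot = 1` and `response_logit_slope = 0`, so that
#' expression, survival and response are all independent of the latent
#' phenotype. Used for type-I-error calibration.
#'
#' @inheritParams generate_cohort
#' @return a `synthetic_cohort`; see [generate_cohort()].
#' @export
generate_null_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  params$effect_size <- 0
  params$hazard_ratio_cold_vs_hot <- 1
  params$response_logit_slope <- 0
  generate_cohort(params)
}

# Upper bound u of a Unif(0, u) censoring time such that the marginal
# probability of censoring before an exponential event equals `target`.
# P(C < T) for T ~ Exp(rate) and C ~ Unif(0, u) is (1 - exp(-rate*u))/(rate*u),
# which decreases from 1 (u -> 0) to 0 (u -> Inf).
.calibrate_uniform_censoring <- function(target, rates, weights) {
  pcens <- function(u) {
    sum(weights * (1 - exp(-rates * u)) / (rates * u)) - target
  }
  lo <- 1e-8 / max(rates)
  hi <- 1 / min(rates)
  while (pcens(hi) > 0) hi <- hi * 2  # pcens decreases with u
  uniroot(pcens, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, %d signatures (%s hot)\n",
              nrow(x$expression), ncol(x$expression), length(x$signatures$sets),
              paste0(sum(x$truth == "hot"))))
  invisible(x)
}
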