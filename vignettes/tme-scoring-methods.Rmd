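---
title: "Methods: TME infiltration scoring and the prognostic TME score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME infiltration scoring and the prognostic TME score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeprofiler)
```

## The problem

Bulk tumor transcriptomes mix malignant cells with the immune and stromal
cells of the tumor microenvironment (TME). Tumors with heavy immune
infiltration ("hot") and sparse infiltration ("cold") behave differently:
they carry different prognoses and respond differently to checkpoint
immunotherapy. `tmeprofiler` implements a complete workflow for
characterizing this axis from a log-scale expression matrix plus survival
annotation:

1. **ssGSEA** scores each sample against a collection of immune-cell
   signature gene sets;
2. **consensus PAM clustering** of the enrichment profiles partitions the
   cohort into TME phenotypes;
3. **moderated differential expression** contrasts the two phenotypes and a
   strict filter (`adj_p < 0.01`, `|logFC| > 1`) defines the TME-associated
   genes;
4. a **univariate-Cox filter** (`p < 0.05`) keeps the prognostic subset,
   which is consensus-clustered into gene clusters;
5. each gene cluster is summarized by the **first principal component** of
   its standardized expression, and the per-cluster PC1 scores are combined
   into a signed **TME score**:
   `score = sum(PC1, clusters with HR > 1) - sum(PC1, clusters with HR < 1)`;
6. the score is **dichotomized** into high/low groups, which are compared by
   Kaplan-Meier/log-rank, Cox models, and response-association tests.

## The ssGSEA statistic

For one sample, genes are ranked by decreasing expression (ties get average
ranks; remaining ties break lexicographically by gene id, so scores are
reproducible to the bit). Walking down that list, a running sum gains
`r^alpha / sum(in-set r^alpha)` at each in-set gene (r is the gene's rank,
higher expression = larger r) and loses `1/(N - m)` at each of the `N - m`
out-of-set genes. The score is the *sum* of the running-sum values over all
N positions, so a set concentrated at the top of the ranking scores high.
With `alpha = 0` the statistic depends on rank positions only; the default
`alpha = 0.25` is the weight in common use. Scores are reported
unnormalized; `minmax_normalize()` maps a whole matrix affinely onto [0, 1]
when comparability across cohort runs matters (whether to normalize before
clustering is exposed as a flag because either choice is defensible — the
clustering is distance-based and unaffected by a global affine map).

The ESTIMATE-style summary is the sum of an immune-set and a stromal-set
ssGSEA score per sample; it proxies total non-tumor content. The purity
transformation applied by the original ESTIMATE method is out of scope.

## Consensus clustering and the number of clusters

`consensus_cluster()` draws `item_fraction` (default 0.8) of the items
without replacement `n_resamples` (default 100) times, clusters each
subsample with PAM, and records for each item pair the fraction of
co-sampled runs in which the pair co-clustered. PAM itself (Rcpp) is the
deterministic BUILD + SWAP local search: SWAP repeatedly applies the single
medoid/non-medoid exchange with the best cost decrease until none improves.
All ties break toward the lowest index. Being a single-exchange local
search, PAM can terminate in a local optimum; on random small instances it
matches the exhaustively enumerated optimum about 95% of the time and never
beats it (the package tests characterize exactly this).

Samples are clustered on Euclidean distance over enrichment profiles; gene
clusters use `1 - Pearson` on standardized expression, so only co-expression
shape matters.

**Choosing k.** The classical consensus-CDF "delta area" is computed and
reported per k, but it is not used for selection: when a crisp cluster is
forced to split, the split is placed differently in every resample, which
*inflates* the next CDF area — on clean two-blob data every delta area stays
above the conventional 0.05 threshold and a "largest k with large delta"
rule runs away to `k_max`. Selection instead uses the proportion of
ambiguous clustering (PAC): the fraction of item pairs whose consensus lies
strictly inside (0.1, 0.9). The selected k is the smallest candidate with
PAC at most 0.1 (at most 10% ambiguous pairs); if no candidate clusters
crisply, the floor (smallest k, i.e. 2) is returned. On simulated blob data
this selects 2 for two blobs, 3 for three blobs, and the floor for a single
Gaussian blob.

The pipeline always *uses* the k = 2 sample partition for the
differential-expression contrast — the workflow is built around two TME
phenotypes — while reporting the PAC-selected k as a diagnostic. Cluster
"1" is relabeled to be the immune-high cluster (highest mean enrichment),
and gene cluster "1" the one most positively correlated with overall immune
enrichment, so labels are comparable across runs.

## Moderated differential expression

Per gene, a two-group comparison on log expression with empirical-Bayes
variance moderation: pooled residual variances are shrunk toward a prior
`s0^2` with prior df `d0` estimated by matching the mean and variance of
`log s_g^2` to a scaled inverse-chi-square prior (trigamma inversion; no
positive solution means `d0 = Inf`, a single shared variance). The
moderated t has `d0 + d_g` degrees of freedom. `prior_df = 0` recovers the
ordinary pooled t exactly; `prior_df = Inf` makes the t ordering equal the
|logFC| ordering. The tests cross-check the whole fit against limma on
random matrices. The DEG filter applies *strict* inequalities
(`adj_p < 0.01`, `|logFC| > 1`), and logFC is reported as cluster 1 minus
cluster 2 (recorded in the result's metadata).

## The TME score

Prognostic genes are consensus-clustered; each cluster's expression block is
z-scored per gene and summarized by the samples' projection on the leading
singular vector (PC1), with the sign fixed so PC1 correlates positively with
the cluster's mean z-score (PCA signs are otherwise arbitrary). Each
cluster's prognostic direction comes from a univariate Cox fit of its PC1
(cluster-level, not per-gene votes); clusters with HR > 1 enter the score
with `+`, clusters with HR < 1 with `-`. A cluster with HR exactly 1 has no
direction and is placed on the protective side with a warning.

As written, the signed sum makes *high* score mean *more risk-cluster
signal*. The pipeline's default orientation (`score_orientation =
"high_good"`) additionally fits a univariate Cox model to the raw score and
flips the global sign when its coefficient is positive, so that a high TME
score always marks good prognosis — matching the convention in which a high
TME score is protective (HR < 1 in the forest plot). The raw formula
convention is available via `score_orientation = "formula"`, and the applied
orientation is recorded in the provenance.

## Dichotomization and cutpoint overfitting

`dichotomize_score()` implements the maximally selected log-rank statistic:
every cut between consecutive distinct score values that leaves at least
`min_group_frac` (default 10%) of samples per side is scored by the
two-group log-rank statistic, and the cut maximizing |statistic| wins (ties
to the lowest cut; candidates are rank-based, so monotone transforms of the
score change nothing).

The *pipeline default*, however, is the median split, for a reason worth
stating. The prognostic gene filter has already consulted the cohort's
survival: among hundreds of candidate genes it preferentially keeps those
whose within-phenotype noise happens to align with survival. Averaged over
hundreds of selected genes, that aligned noise becomes a systematic
component of each cluster's PC1 — inside each phenotype group the score
ranks samples partly by their observed survival. A survival-maximizing
cutpoint then chases this leaked ordering and lands far from the phenotype
boundary, producing strongly unbalanced groups that reflect early-death
status rather than biology, even when the score itself separates the
phenotypes perfectly. On synthetic cohorts the median split recovers the
latent phenotype essentially perfectly while the maximally selected cut
frequently does not, with no loss in survival separation. The maximally
selected cut remains available (`dichotomize_method = "maxsel"`) and is the
right tool when the score was built on *independent* data.

## Statistical routing

`compare_groups()` reproduces the analysis convention: Shapiro-Wilk
normality per group at alpha 0.05 (a fixed level; constant groups count as
non-normal); all-normal routes to Student's t (pooled variance) or one-way
ANOVA, otherwise Wilcoxon rank-sum or Kruskal-Wallis. Wilcoxon p-values are
exact for combined n <= 20 without ties, tie-corrected normal approximation
otherwise. The chi-square contingency test is Pearson's without continuity
correction. Distance correlation uses the standard double-centered
(biased) estimator; note its positive bias under independence (mean around
0.2 at n = 50), which is a property of the estimator, not a bug.
Over-representation uses the one-sided hypergeometric tail with BH
adjustment across sets; term databases are not bundled — any GMT works.

Survival machinery (Kaplan-Meier, log-rank, Cox with Breslow ties and Wald
95% intervals) is delegated to the `survival` package behind the package's
interfaces.

## The synthetic cohort generator

`generate_cohort()` draws the conditions the workflow is validated under:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 120 | cohort size |
| `n_genes` | 1000 | background gene count |
| `n_signatures` x `genes_per_signature` | 28 x 25 | immune-cell signatures (disjoint) |
| `hot_fraction` | 0.5 | share of immune-hot tumors |
| `effect_size` | 3 | log2 shift of signature genes in hot tumors |
| `noise_sd` | 1 | per-gene, per-sample log2 noise |
| `baseline_hazard` | 0.02/month | hot-group exponential event hazard (median ~35 months) |
| `hazard_ratio_cold_vs_hot` | 2 | excess hazard of cold tumors |
| `censor_rate` | 0.3 | expected censored fraction (uniform censoring, calibrated analytically) |
| `response_logit_slope` | 2 | log-odds gain of objective response (CR/PR) in hot tumors, over a 25% cold-group response rate |

Gene baselines are N(6, 2) on log2 scale, noise is iid Gaussian, signatures
are disjoint blocks — the simplest model with the block structure ssGSEA
assumes. Survival is exponential with independent uniform censoring whose
upper bound solves the closed-form censoring probability for the target
rate. One integer seed drives every draw, and generation is byte-identical
given identical parameters. `generate_null_cohort()` zeroes the expression
shift, the hazard ratio and the response slope, for type-I-error
calibration.

What the generator does *not* emulate: gene-gene correlation beyond the
phenotype block structure, library-size or batch effects, non-proportional
hazards, overlapping signatures, and real signature collections. Passing
tests on these cohorts therefore demonstrate correctness of the machinery
and calibration of the statistics under the assumed model — not performance
on real tumors.

## Numerical choices and degenerate inputs

* ssGSEA requires each set to overlap the matrix in at least `min_overlap`
  (default 2) genes and to leave a non-empty complement.
* `minmax_normalize()` rejects constant matrices.
* PAM validates symmetry, non-negativity and a zero diagonal; consensus
  clustering needs at least 4 items and `k_max` below the item count.
* Cox fits: Breslow tie handling everywhere; monotone likelihood (perfect
  separation) is flagged and the coefficient capped at |beta| = 15.
* `pc1_signature()` drops zero-variance genes with a warning and refuses
  signatures with fewer than 2 overlapping genes; single-gene clusters in
  the pipeline fall back to the gene's z-score.
* All-constant genes in `moderated_de()` take their variance entirely from
  the prior and are flagged.
* Problem sizes used in the validation suite (cohorts of 30-120 samples,
  200-1000 genes, 100-500 simulation replicates) were chosen to give stable
  Monte-Carlo estimates for the calibration checks while keeping the whole
  suite quick to run.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_params(seed = 1))
res <- analyze_cohort(co$expression, co$clinical, co$signatures,
                      pipeline_config(seed = 1))
res
adjusted_rand_index(res$scored$score_group, co$truth)
res$survival_report$cox
```

The `analysis/` directory of the source repository runs the same workflow
as six numbered scripts writing their tables under `results/`, and
`scripts/acceptance.R` recomputes the headline quantities from scratch for
any seed.

## Known limitations

* PAM is a local search; global optimality is not guaranteed (and is
  occasionally missed on small instances).
* The TME score pipeline reuses one cohort for gene selection, direction
  estimation and cutpoint selection; out-of-cohort validation is the user's
  responsibility, and the maximally selected cutpoint in particular should
  only be trusted on independent data.
* Distance correlation is reported without a p-value; pair it with a
  permutation test if inference is needed.
* TIDE/SubMap-style response prediction is out of scope; only the
  association tests around externally supplied response labels are
  implemented.
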