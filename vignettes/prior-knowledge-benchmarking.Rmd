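---
title: "Benchmarking prior-knowledge feature selection with PKBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking prior-knowledge feature selection with PKBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PKBench)
```

# Scope and model

PKBench benchmarks feature selectors for classifying gene expression
samples, with emphasis on selectors that integrate prior biological
knowledge. The package assumes **normalized** expression values on a
roughly Gaussian (log-like) scale in a genes × samples matrix with
per-sample class labels; normalization itself is out of scope, as are
live web-service knowledge bases — all prior knowledge is read from
local files (gene–term association TSVs, GMT membership libraries,
pathway edge lists), which keeps every run reproducible offline.

Three integration depths are implemented:

* **Modifying** selectors wrap a statistical ranking with a
  knowledge-base step: restricting the gene universe before ranking
  (prefilter), dropping irrelevant genes after ranking (postfilter), or
  appending strongly associated genes to a statistical prefix
  (extension). For subset-independent statistics such as per-gene
  variance or ANOVA F, prefiltering and postfiltering provably coincide,
  and the test suite asserts that equivalence.
* **Combining** selectors alter the score itself: multiplication of the
  statistical score by the association score
  (`s_i = s_i^trad * s_i^kb`), or feature-specific penalty factors
  `w_i = 1 - s_i^kb` (clipped to `[epsilon, 1]`) inside an
  L1-regularized linear classifier. A monotone-decreasing map from
  association score to penalty is the minimal construction with the
  intended behaviour — well-supported genes are penalized less; the
  linear clip is the simplest such map and is therefore the one
  implemented.
* **Network** selection replaces genes by pathways: a pathway is
  class-relevant when its member genes' expression associates with the
  classes, quantified as the mean ANOVA F over measured members and
  calibrated by a label-permutation null. Selected pathways become
  per-sample *activity* features: the mean z-scored expression of the
  measured members. This is deliberately a simplified activity score —
  no condition-responsive member subset is searched — and is documented
  as such; with mixed up/down-regulated members, averaging can cancel
  signal.

The degree-percentile **connectedness score** summarizes network
topology alone: within a pathway of *n* members a gene's percentile
rank is `rank(degree, average ties) / n`, a value in (0, 1], and the
gene score is the mean percentile over the pathways containing the
gene. "Connectedness" is realized as vertex **degree**: it is the
simplest statistic under which hub genes with many interactions score
highest, and it makes the brute-force oracle in the tests exact.
Isolated member genes are kept and rank lowest — membership without
interactions is still membership. Alternative centralities are not
implemented.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minScore` | 0 | association-score threshold for relevance (unitless, [0,1]) |
| `aggregation` | `max` | per-gene aggregation over search terms; a gene strongly tied to *any* term is relevant, `mean` available |
| `missingPolicy`, `epsilon` | `epsilon`, 0.001 | combined score for genes without a KB record; `epsilon` keeps them ranked below covered genes of equal statistical score instead of collapsing them all to 0 |
| `lambda` | 0.05 | Lasso regularization strength (on glmnet's standardized scale) |
| `nPermutations` | 200 | label shuffles behind the empirical pathway p-value; granularity is 1/(B+1) |
| `k` (CV folds) | 10 | tenfold stratified cross-validation |
| `sizes` | 1:20 | feature-set sizes swept from the top of each ranking |
| kNN `k` | 3 | fixed; the other classifiers run at their packages' conventional defaults |

Genes absent from a knowledge base get *no* score entry rather than an
implicit 0; each consumer decides its own default, which keeps the
"uncovered" and "scored 0" cases distinguishable.

# Numerical and procedural choices

* **Determinism.** Every ranking is sorted by score descending with
  gene-identifier ascending as tie-break; every stochastic operation
  takes an explicit seed and derives child streams from it. Two
  benchmark runs with the same config and seed produce byte-identical
  analytic outputs (only `logs/` carries timestamps and runtimes).
* **ANOVA edge cases.** The vectorized F statistic ignores missing
  entries per gene. A gene with zero within-class variance but distinct
  class means has an infinite F; it is capped at 1e12 so ranking scores
  stay finite. All-constant genes get F = 0, as do genes left without
  observations in some class.
* **Missing values.** Thresholds in `filterMissing()` are *fractions*
  (absolute counts are not supported), and samples are filtered before
  features so that feature missingness is judged on the surviving
  samples. Selectors that need complete data (Lasso) impute per-gene
  means; inside cross-validation, imputation and z-scaling parameters
  are fit on the training folds only — a leakage canary test pins this
  down.
* **Folds.** Stratified assignment deals each class round-robin over a
  seed-shuffled, id-sorted order, so per-fold class proportions deviate
  by less than one sample and the assignment is invariant to column
  order. The fold assignment is shared across feature-set sizes and
  across selectors for a given (dataset, seed), making comparisons
  paired.
* **Pathway selection** reports the top *n* pathways with their
  empirical p-values rather than thresholding on p: the permutation
  granularity at small B makes a fixed cut-off brittle, and the
  benchmark consumer wants a fixed-size feature space. p-values use the
  add-one estimator (1 + #{perm ≥ obs})/(B + 1).
* **Extension rankings** concatenate a statistical prefix and an
  association-ordered tail; the two score scales are incommensurable,
  so the result carries ordinal scores (n..1) and flags this in its
  metadata.
* **"Linear regression"** in the classifier panel is realized as
  multinomial logistic regression: a linear model used for class
  prediction. Macro-averaged F1 is reported alongside accuracy because
  benchmark label sets are frequently multi-class and imbalanced.
* **Enrichment** uses the one-sided hypergeometric tail, BH adjustment
  (the conventional choice where only "adjusted p" is specified), a
  0.05 adjusted-p filter and the combined score `-ln(p) * z` with z the
  deviation of the observed overlap from its hypergeometric expectation
  in standard-deviation units.
* **Kendall's W** applies the standard tie correction with average
  ranks. Inside a benchmark run, selectors may rank different gene
  universes (prefiltering shrinks them); W is computed on the common
  intersection and the snapshot records the intersection size.

# The synthetic study

`simulationSpec()` defaults define the reference conditions used by the
tests and the acceptance script: 1000 genes × 100 samples in 2 balanced
classes, 10 informative genes shifted by 2 within-class standard
deviations (random direction per gene), no missingness, a knowledge
base scoring planted genes ≈ 0.9 and a random half of the null genes
≈ 0.1 (jitter ± 0.05, clipped to [0, 1]), and 10 preferential-attachment
pathways of 20 genes with 10 % designated hubs, the first pathway built
from the planted genes. These sizes are large enough for stable rank
statistics yet small enough that a full simulation sweep runs in
seconds; smaller variants (tens of genes, tens of samples) are used
where a test only needs structural properties.

The generator emulates: class-conditional Gaussian expression on a
normalized scale, partial and noisy knowledge-base coverage, hub-heavy
pathway topology, uniform missingness, and a related second cohort
(fresh noise, optional global mean shift). It does **not** emulate
count overdispersion, gene–gene correlation outside pathways, batch
structure beyond a global shift, annotation bias, or label noise.
Passing tests therefore demonstrate algorithmic correctness and the
expected qualitative behaviour of prior-knowledge integration — not
performance claims about real cohorts, where knowledge-base quality and
violated distributional assumptions dominate.

# Pipeline and extensibility

`runBenchmark()` executes preprocessing → coverage reporting → each
selector (wall-clock timed) → size-sweep CV → optional cross-dataset
validation → concordance/overlap/enrichment comparisons, writing one
run directory with `preprocessing/`, `coverage/`, `rankings/`,
`metrics/`, `enrichment/` and `logs/` plus an effective-config
snapshot. A selector failure is logged and isolated; the remaining
selectors complete. Configuration is layered INI: a complete main file
plus a user file naming only the overridden keys, validated against a
strict schema that names unknown keys. Custom components plug in
through `registerSelector()` / `registerClassifier()` and are then
addressable from configs and included in all comparisons.

# Known limitations

* Pathway activity averages all measured members; bidirectional
  pathways can self-cancel.
* The penalized Lasso ranks zero-coefficient genes by penalty only —
  informative but unsupported genes are indistinguishable below the
  support.
* Empirical pathway p-values are lower-bounded by 1/(B+1).
* Identifier mapping is table-driven; no fuzzy or versioned mapping.
* The enrichment module tests overrepresentation only; no ranked GSEA.
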