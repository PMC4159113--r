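---
title: "Methods: preactivated-gene detection and pathway signature scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preactivated-gene detection and pathway signature scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preactivation)
```

## The scientific question and the analysis model

Cells that undergo an epithelial-to-mesenchymal transition (EMT) revert to a
de-differentiated, stem-like state and become broadly chemoresistant. One
proposed mechanism is that such cells keep their oxidative-stress response —
classically a *reaction* to reactive oxygen species (ROS) — switched on
constitutively, for instance through PERK kinase activity driving the Nrf2
antioxidant program. The computational signature of that claim has three
parts, and this package implements each as a separate, composable module:

1. **Preactivation in a controlled experiment.** Profile differentiated and
   de-differentiated cells with and without an oxidant. Call genes *induced*
   in a genotype when the oxidant raises their mean log2 expression by more
   than a fold threshold; call genes *basally up* when the untreated
   de-differentiated cells exceed the untreated differentiated cells by the
   same threshold. The *preactivated* set is the intersection: stress-response
   genes that are already high without stress. If preactivation is real, that
   intersection is far larger than chance — quantified by the hypergeometric
   upper tail.
2. **A transferable pathway signature.** The pathway's transcriptional
   footprint is defined operationally: the `top_n` genes most down-regulated
   by a pathway inhibitor in de-differentiated cells. That gene list can be
   evaluated in any expression dataset.
3. **Clinical read-out in cohorts.** Each patient gets a score — the sum of
   log2 expression over the signature genes — and cohorts are stratified into
   the top and bottom score fractions. If the pathway matters clinically,
   high-scoring patients should respond worse to therapy and survive shorter,
   tested with responder fractions and the Mantel–Cox (log-rank) test.

## Differential calling

Calling is deliberately threshold-only: a gene is up-regulated when
`mean(log2 expr | group A) − mean(log2 expr | group B) > log2(fc_threshold)`,
a strict inequality (a gene at exactly 2-fold is *not* called at the default
threshold of 2). Replicates enter only through their mean; no variance
moderation or multiple-testing control is applied, because the downstream
overlap statistics operate on the called sets, not on per-gene p-values. The
"differentially expressed" set between genotypes is the union of the up- and
down-calls at the same threshold. Fold changes are computed as differences of
mean log2 values (i.e. log fold changes of geometric means), the standard
convention for log-scale array data and the scale on which the signature
score is defined.

## Overlap statistics

For sets of sizes K and n with overlap k in a universe of N measured genes,
the enrichment statistic is the hypergeometric upper tail
P(X ≥ k), X ~ Hypergeom(N, K, n). `hypergeom_tail_upper()` evaluates each
term as `exp(lchoose(K,i) + lchoose(N−K, n−i) − lchoose(N,n))` and sums the
tail starting from its far (smallest) end, so the result is accurate to
absolute 1e-12 down to the smallest normal doubles; observed overlaps of the
magnitude this analysis produces (p ≈ 1e-50) are represented exactly rather
than underflowing to 0. The tests verify agreement with direct
binomial-coefficient enumeration for every universe size up to 60 and with
`stats::phyper` at published scale.

Two conventions matter and are explicit arguments rather than constants:

* **Universe.** The enrichment p-value depends on N. The pipeline defaults to
  all genes measured in the experiment at hand, which is the only universe
  that is always well defined; any other universe (e.g. an array's full probe
  complement) can be passed as a gene set or a count. For reference-scale
  inputs (k = 44, K = 181, n = 170) any universe from a few thousand genes
  upward leaves the qualitative conclusion unchanged.
* **Direction.** Only enrichment (upper tail) is tested; depletion is out of
  scope because every claim the pipeline evaluates is an enrichment claim.
  Raw p-values are reported; `bh_adjust()` is available when screening many
  sets at once.

## Signature scoring and stratification

The per-sample score is an unweighted sum of log2 expression over the
signature genes present in the cohort matrix. Summation (rather than rank- or
z-score-based schemes) keeps the score linear in the data and exactly
reproducible from the published definition. Signature genes missing from a
cohort are dropped; the coverage fraction is attached to the result and a
warning is raised below 0.8, because a sum over a materially different gene
set is not comparable across cohorts.

Stratification takes `m = floor(fraction · n)` samples at each extreme
(default fraction 0.15, applied per cohort). Ties are resolved by a single
ascending radix sort on (score, sample id): the low stratum is the first m
entries, the high stratum the last m. This guarantees disjoint, size-m strata
for every input — including the degenerate all-scores-equal case — and makes
the labeling reproducible across platforms and locales.

## The Monte Carlo correlation null

To ask whether two signatures co-vary across a cohort, the observed statistic
is Spearman's rho (Pearson on midranks) between the two score vectors. The
null model resamples **gene sets, not samples**: each of `reps` draws takes a
uniform random subset of the cohort's measured genes, size-matched to the
number of signature genes actually present, scores it, and correlates it with
the fixed second score vector. This preserves the score's gene-count, the
cohort's sample-level correlation structure, and any global expression
gradients — exactly the nuisance structure a sample-permutation null would
destroy. The two-sided empirical p-value uses the add-one rule
`(1 + #{|rho_null| ≥ |rho_obs|}) / (reps + 1)`, so the minimum attainable
p is `1/(reps+1)` and the estimator is never anti-conservative at 0. A seed
is mandatory; given one, results are bit-reproducible. The acceptance tests
verify that under a null cohort (no expression–activity coupling) the p-value
is uniform over 500 independent runs at `reps = 1000`.

## Survival and response

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package behind a records-based interface (`survival_records()`
validates times and event indicators once, at construction). Conventions:
events precede censorings at tied times (the product-limit standard); the
Mantel–Cox statistic is the chi-square form without continuity correction,
referred to 1 degree of freedom. The test suite pins both against
first-principles oracles: a hand-computed product-limit example and an
explicit O/E/V accumulation over event times, plus a 1,000-replicate null
simulation holding the type-I error at 0.05 ± 0.02. Responder fractions count
complete plus partial responses over stratum size; the endpoint label
(overall vs metastasis-free survival) is carried as free text because it
changes nothing computationally.

## What the synthetic generator emulates — and what it does not

`simulate_cellline_experiment()` draws per-gene baselines from
N(7, 1.5²) log2 units, adds fixed effects of `delta = 1.5` log2 units for
the planted sets, and iid N(0, 0.3²) measurement noise, with 3 replicates
per genotype × treatment arm and 10,000 genes by default. The planted set
sizes are the reference design of the analysis: 181 and 170 oxidant-induced
genes, 44 common, 54 preactivated of which 38 uniquely induced, and
847 + 847 genes up/down between genotypes (a 1,694-gene differential union).
The overlap structure is realized by explicit index blocks, so every
containment constraint holds by construction and the generator returns the
truth as `GeneSet` objects. An optional inhibitor arm plants 500
inhibitor-down genes so the signature-derivation stage has a recoverable
truth. With `noise_sd = 0` and `delta > log2(fc_threshold)` recovery is
exact, which the tests assert; at the default noise the recovered counts at
seed 1 (178/170/44/53/37) are frozen as a regression fixture.

`simulate_cohort()` ties three observables to one latent activity
`a ~ N(0,1)` per patient: signature-gene expression (`beta = 0.8` log2 units
per activity SD, residual SD 0.5), exponential survival with rate
`0.05 · exp(log(2.5) · a)` censored administratively at 60 time units, and a
logistic responder model `P(responder) = plogis(1 − 1.5a)` with responders
split evenly between complete and partial. Defaults (200 patients, 5,000
genes, 500 signature genes) give score–activity Spearman correlations above
0.9 and near-certain log-rank detection of the planted hazard ratio.

Neither generator emulates probe-level artifacts, batch effects,
heavy-tailed or count-distributed noise, gene–gene correlation beyond the
single latent factor, competing risks, or informative censoring. Passing the
recovery tests therefore demonstrates that the *pipeline logic* is correct
under its stated model — not that the thresholds are optimal for any
particular real array platform.

## Numerical and design choices

* **Strict thresholds.** ">2-fold" excludes the boundary; boundary genes are
  visible in the per-gene fold-change table the pipeline writes.
* **Quantile normalization ties.** Tied values within a column receive the
  mean of the reference distribution over their tied rank span. Under this
  convention a second normalization pass is an exact no-op only for tie-free
  columns (ties are collapsed to their span mean, which perturbs the column
  multiset once); the idempotence property is therefore stated and tested for
  tie-free data.
* **Deterministic ordering everywhere.** Gene and sample ties break by radix
  (byte-order) sort, independent of locale; derived sets are stored sorted.
* **Missing data are errors.** Cells that fail to parse, signature coverage
  of zero, metadata referencing unknown samples, and preactivation inputs
  violating containment all raise immediately with coordinates or ids, never
  impute.
* **Problem sizes in the tests.** The suite runs the full 10,000-gene
  reference design for zero- and default-noise recovery, 500 × 1000-rep
  Monte Carlo calibration on a 400-gene/50-sample null cohort, 1,000
  log-rank null simulations at 50 + 50 patients, and 40 pipeline-level power
  replicates at 600 genes / 200 patients — sizes chosen so the entire suite
  completes in about a minute on one core while keeping every estimate's
  sampling error well inside its asserted band.

## Limitations

Threshold-only calling has no error control per gene and is sensitive to the
fold threshold near the boundary; the hypergeometric model assumes genes are
exchangeable under the null, which real co-expression violates; summed
scores are platform-dependent (they change under renormalization by a
per-sample constant, though stratification is invariant to monotone
per-cohort transformations); and the Monte Carlo null resamples genes, so it
does not protect against cohort-wide confounders that correlate both
signatures with, say, tumor purity. These are properties of the method being
implemented, stated here so users know where its guarantees end.
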