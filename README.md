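# preactivation

Tools for a recurring question in tumor biology: do de-differentiated
(EMT / mesenchymal-like) cells switch on their oxidative-stress defenses
*before* any stress arrives, and does that preactivation predict how patients
respond to therapy?

The package implements the complete computational chain for that analysis on
bulk expression data, for anyone who wants to run it on their own two-genotype
stress experiments and patient cohorts:

1. **Differential calling** — threshold-based fold-change sets on log2
   expression. A gene is "induced" when its mean log2 expression rises by more
   than `log2(fc_threshold)` (default: strictly >2-fold) between arms.
2. **Preactivated-gene logic** — the intersection construct at the core of the
   analysis: genes induced by an oxidant in differentiated cells that are
   *already* up-regulated in de-differentiated cells without treatment, plus
   the "uniquely induced" remainder once de-differentiated-cell induction is
   removed.
3. **Overlap statistics** — the upper-tail hypergeometric probability
   P(X ≥ k) for an overlap of k between sets of sizes K and n in a universe of
   N measured genes, evaluated with log-gamma binomials and tail-first
   summation so that p-values far below 1e-300 remain exact. Fold enrichment
   is k/(K·n/N).
4. **Signature scoring** — a pathway signature is the top-n genes (default
   500) moved by a perturbation (e.g. a PERK inhibitor); a patient's score is
   the **sum of log2 expression over the signature genes**, strata are the top
   and bottom 15% of scores, and signature–signature association is Spearman's
   rho with an empirical p-value from size-matched random gene sets (Monte
   Carlo, add-one rule).
5. **Survival and response** — Kaplan–Meier curves, the Mantel–Cox (log-rank)
   test between high/low strata, and responder fractions
   (complete + partial response).
6. **A synthetic-data generator** — planted cell-line experiments and latent-
   activity patient cohorts with known ground truth, so every stage of the
   pipeline is testable end-to-end without any external download.

## Worked example

Simulate the reference experiment (two genotypes × vehicle/oxidant arms,
3 replicates, 10,000 genes, noise SD 0.3) and run the preactivation analysis:

```r
library(preactivation)

sim    <- simulate_cellline_experiment(cellline_sim_params(seed = 1))
report <- run_preactivation(sim$expression)
report
#> Preactivation analysis (fold-change threshold 2 )
#>   ros_induced_diff     178 genes
#>   ros_induced_dediff   170 genes
#>   dediff_up            818 genes
#>   dediff_down          836 genes
#>   differential         1654 genes
#>   common_induced       44 genes
#>   preactivated         53 genes
#>   uniquely_induced     37 genes
#>   common_induced: p_upper = 7.39e-40
#>   preactivated: p_upper = 1.99e-17
```

The generator plants 181/170 induced genes, 44 common, 54 preactivated and a
1,694-gene differential union; at the default noise level the 2-fold caller
recovers 178/170/44/53 of them with no false positives (at `noise_sd = 0`
recovery is exact). `p_upper` is the hypergeometric upper tail of each overlap
against the 10,000 measured genes: both overlaps are far beyond chance, which
is the statistical signature of preactivation.

The cohort half: a latent pathway activity drives signature-gene expression,
hazard (HR 2.5 per activity SD) and therapy response in 200 simulated
patients. Score, stratify at 15%, and compare the extremes:

```r
co   <- simulate_cohort(cohort_sim_params(seed = 1))
crep <- run_cohort_analysis(co$expression, co$signature,
                            survival = co$survival, response = co$response)
crep
#> Cohort analysis: 200 samples (high=30, low=30, mid=140), coverage 1.00
#>   log-rank high vs low: chisq = 48.114, p = 4.02e-12
#>   responder fractions: high=0.20, low=0.97
```

High-signature patients have sharply worse survival and far fewer responders
than low-signature patients — the direction the latent-activity model plants.

A single overlap statistic is just as accessible directly:

```r
hypergeom_tail_upper(44, 181, 170, 20000)
#> [1] 2.124324e-52
```

## Command line

`exec/preact` wraps the same functions for shell use:

```sh
preact simulate --kind cellline --seed 1 --out sim/
preact preactivation --expr sim/expression.tsv --meta sim/metadata.tsv --out out/
preact overlap --gmt sets.gmt --universe 20000 --json
preact cohort --expr cohort.tsv --gmt signature.gmt --surv survival.tsv \
              --reps 1000 --seed 1 --out cohort_out/
```

Inputs are plain TSV matrices (`gene_id` + sample columns), TSV metadata
keyed by `sample_id`, and GMT gene sets.

## Documentation

`vignettes/preactivation-methods.Rmd` describes the model assumptions, the
tunable parameters, what the synthetic generator does and does not emulate,
and the numerical conventions (tie handling, strictness of thresholds,
universe choice).
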