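---
title: "Kinase–substrate edge biomarkers: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase–substrate edge biomarkers: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgekin)
```

## The edge-feature model

A kinase–substrate interaction network supplies directed gene pairs
(u, v). For a sample j belonging to class k (e.g. ER-negative), the edge
feature of the pair is the product of the two class-conditionally
standardized expression values,

$$\mathrm{edge}\langle u\!-\!v\rangle_{j,k} \;=\;
  \frac{x_{u,j,k}-\mu_{u,k}}{\sigma_{u,k}}\cdot
  \frac{x_{v,j,k}-\mu_{v,k}}{\sigma_{v,k}},$$

with $\mu_{g,k}$ the within-class arithmetic mean and $\sigma_{g,k}$ the
**uncorrected** (divide-by-$n_k$) standard deviation. Two consequences
shape everything downstream:

1. **Mean–correlation identity.** Averaging an edge feature over the
   samples of class k gives exactly the within-class Pearson correlation
   of u and v. Edge features therefore decompose differential
   co-expression into per-sample quantities that can enter classifiers
   and survival models like any other covariate. This identity is asserted
   to 1e-9 in the test suite on random matrices, and the vectorized
   implementation is checked against a per-sample scalar loop to 1e-12.
2. **Class-conditional construction needs labels.** A sample can only be
   standardized against the parameters of *its own* class, so edge values
   are defined for labelled cohorts. How an unlabelled new sample should
   be transformed is undefined in this model and the package deliberately
   does not guess.

Node features are the same genes' pooled (both classes together)
gene-level z-scores, optionally after `log2(x + pseudocount)` for raw
abundance input. The pooled z-score also uses the uncorrected standard
deviation, keeping one convention throughout (for two samples the z-scores
are then ±1). Genes constant across the cohort are dropped; genes constant
*within a class* would make their edges undefined, so all edges touching
such a gene are excluded, with counts reported — silent exclusion would
corrupt downstream feature counts.

Both parameter provenances co-exist: `edge_transform()` defaults to
full-cohort class parameters (reproducing the published order of
operations), and accepts training-only parameters so that repeated-split
evaluation can avoid leaking test samples into feature construction
(`mode = "cv-safe"` in `mc_cv_cindex()`). The `provenance` field of the
feature table records which was used.

## Differential selection

Selection proceeds in the published two-step order:

* **Student's t prefilter** (pooled variance, two-sided, unadjusted
  p < 0.05). It is applied once on the full cohort *before*
  cross-validation. This induces a known optimism in the subsequent
  cross-validated AUC: the prefilter has seen every label, so even on
  label-permuted data the surviving features are slightly class-correlated
  (we measure out-of-fold AUC near 0.7 on permuted labels when the
  prefilter is included). The package follows the published order for the
  selection result itself and documents the caveat; the null-calibration
  test therefore applies the permutation to the cross-validated LASSO
  alone, which is correctly centred at AUC 0.5.
* **LASSO logistic regression** (`glmnet`, binomial family) with
  stratified, seeded k-fold cross-validation (default 5). Stratification
  is not part of the published description but with imbalanced classes
  (the motivating cohort is roughly 77:23) unstratified folds can lose the
  minority class entirely, so folds are stratified by construction. The
  penalty is chosen by minimum cross-validated deviance
  (`lambda_rule = "1se"` is available); out-of-fold linear predictors are
  pooled across folds into a single ROC for the reported AUC (AUC is
  invariant under the monotone logistic link, and ties count one half);
  the final signature is the non-zero support of a full-data refit at the
  chosen penalty. Features are standardized internally by `glmnet` and
  coefficients are reported on the original scale.

## Prognostic evaluation

`mc_cv_cindex()` implements repeated random splitting (Monte-Carlo
cross-validation) rather than disjoint fold partitions: `n_iter` seeded
train/test splits at a configurable train fraction (0.8 and 0.5 are the
two published regimes), a random survival forest per model variant per
split, and Harrell's C-index of the predicted risk (sum of the ensemble
cumulative hazard) on the held-out samples. Splits are resampled (and
logged) in the rare case a partition contains no events. All variants see
the identical split sequence, so paired comparisons across variants are
legitimate; `compare_variants()` applies two-sided Wilcoxon rank-sum tests
(exact for small samples without ties, normal approximation with tie
correction otherwise, following `stats::wilcox.test`; no continuity
correction, so identical distributions give p = 1).

Forest hyperparameters are not dictated by the method being reproduced;
the defaults are 1000 trees, log-rank splitting, and a minimum terminal
node size of 15 — customary survival-forest settings — all configurable
and recorded. The forests are fitted with `ranger` single-threaded with a
per-split seed, which makes every C-index table byte-reproducible.

Per-feature inference uses `survival`: Cox partial likelihood with Efron
tie handling, HR = exp(beta) with Wald 95% CI and p; categorical
covariates are coded against the most frequent level as reference;
monotone-likelihood non-convergence is flagged in the result rather than
returned silently. `km_median_split()` dichotomizes at the cohort median
with the `<=`-median-goes-low tie rule (the interpolated median of an even
cohort), requires at least two samples per group, and reports the log-rank
chi-squared with its p-value plus the product-limit curves.

## Enrichment

`hypergeom_enrich()` computes the upper-tail hypergeometric probability
P(X >= k) for the overlap k between the selected genes (edges contribute
both endpoints, deduplicated) and each gene set, intersected with a
configurable universe. The default universe is all network genes present
in the expression matrix — the selection can only ever produce genes from
that pool, so a whole-genome background would overstate significance.
Benjamini–Hochberg adjustment is applied across the tested sets and the
0.05 significance flag refers to the adjusted p by default (a flag
switches to raw p).

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` emulate exactly the statistical
structure the analysis assumes, not real RNA-seq data:

* independent Gaussian baseline expression per gene
  (`baseline_mean`, `baseline_sd`), so planted effects are the only
  structure present;
* planted class-2 mean shifts (`node_effects`) and planted class-specific
  correlations per kinase–substrate pair (`edge_effects`, bivariate
  Gaussian draws per class). Pairs sharing a gene are rejected at
  validation: draws are assigned sequentially, and a later draw would
  silently destroy an earlier pair's correlation;
* event times from a Weibull proportional-hazards model,
  $T = \lambda(-\log U / e^{\mathrm{lp}})^{1/\kappa}$, with the linear
  predictor a chosen combination of node and edge features — the edge
  features being computed with the package's own transform, so the planted
  hazard lives on exactly the quantity the analysis estimates. The
  published analyses fit Cox models but state no generative model; a
  Weibull baseline is the standard proportional-hazards simulation;
* independent Uniform(0, c) censoring with c calibrated by bisection to
  the requested censored fraction (within ±0.02 at moderate n) — nothing
  in the source method constrains censoring structure, so the simplest
  independent mechanism is used;
* one categorical "stage-like" covariate with configurable per-class
  frequencies, to exercise multivariate Cox models and the Clinical-only
  variant.

Every draw is wrapped in `withr::with_seed`; the outcome stream uses
seed + 1 so expression and survival are independent yet both reachable
from the single spec seed. Identical spec + seed gives byte-identical
cohorts.

What the generator does **not** emulate: negative-binomial count noise,
batch effects, copy-number structure, gene–gene correlation beyond the
planted pairs, or realistic effect sizes — no effect-size information is
available for the motivating cohort's 46-feature signature, so defaults
(|rho| = 0.6–0.8, delta = 1, beta = 1) are chosen for test power, not
biological realism. Passing tests therefore demonstrate correctness of the
machinery under its own assumptions, not performance on real tumours.

## Numerical and degenerate-case choices

* Uncorrected (÷n) standard deviations throughout the transform; the
  pooled z-score uses the same convention for coherence.
* Zero-variance genes: dropped from normalization (pooled) or removed with
  all their edges (within-class), both with logged counts; features with
  zero pooled variance are dropped by the t prefilter (their statistic is
  undefined).
* Prefilter boundary: `alpha = 1` retains every testable feature.
* AUC and C-index ties count one half; C-index comparability follows the
  standard censoring rule (the earlier time must be an event).
* Median split sends values equal to the median to the low group.
* Edge IDs use an ASCII hyphen (`SRC-OCLN`); gene symbols containing
  hyphens are handled through the explicit kinase/substrate columns kept
  alongside every edge feature, with hyphen-splitting only as a fallback
  for bare ID vectors.
* The `select_features()` signature comes from a full-data refit whose
  penalty was tuned on the same data — faithful to the published
  procedure, and flagged here as an optimism caveat.

## Problem sizes used in the shipped checks

The test-suite and acceptance experiments run at desk scale, chosen once:
recovery of five planted differential edges (|rho| = 0.8 per class,
opposite signs) among 95 noise pairs at 200 samples/class over 20 seeds;
survival-forest discrimination on a 15-pair network at 100 samples/class
with two hazard-bearing edges (beta = 1), 100 random 80/20 splits, 500
trees; Cox recovery at n = 1000; log-rank null calibration over 200
cohorts of n = 60; median-split detection at 400 samples over 20 seeds.
These sizes give comfortable Monte-Carlo margins for the properties being
asserted while keeping a full run in a few minutes on one core.

## Known limitations

* Prediction for unlabelled samples is undefined (class-conditional
  transform); the package refuses to guess.
* Overlapping planted correlations would need a joint multivariate
  specification, which is out of scope; validation rejects them.
* The t prefilter outside CV and the full-data penalty refit reproduce the
  published procedure at the cost of optimistic internal AUC estimates;
  prefer `mode = "cv-safe"` evaluation and external validation cohorts for
  honest performance claims.
* Gene identity is exact, case-sensitive symbol matching; no cross-database
  identifier reconciliation is attempted.
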