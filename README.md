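# edgekin

Kinase–substrate **edge biomarkers** for two-class cancer cohorts: build
per-sample edge features from expression data, select the node and edge
features that differ between two patient classes (e.g. ER-positive vs
ER-negative breast cancer), and evaluate their prognostic value with
survival models.

## The idea

Single-gene ("node") markers miss information carried by the *relationship*
between a kinase and its substrate. Given a directed kinase→substrate pair
(u, v) and a sample j in class k, edgekin computes the edge feature

```
edge<u-v> = (x_{u,j,k} - mu_{u,k}) / sigma_{u,k} * (x_{v,j,k} - mu_{v,k}) / sigma_{v,k}
```

where mu and sigma are the within-class mean and *uncorrected*
(divide-by-n) standard deviation of each gene. The class average of an edge
feature is exactly the within-class Pearson correlation of the pair, so an
edge feature is a per-sample decomposition of differential co-expression.
Downstream, the package provides:

- **Differential selection** — pooled-variance Student's t prefilter
  (p < 0.05, unadjusted), then an L1-penalized (LASSO) binomial classifier
  with stratified 5-fold cross-validation; the penalty is chosen by minimum
  CV deviance, the pooled out-of-fold predictions give an honest AUC, and
  the final full-data refit yields the non-zero-coefficient signature.
- **Prognostic evaluation** — repeated random 80/20 (or 50/50) splits;
  per split a random survival forest (log-rank splitting) is trained per
  model variant (Clinical, KinSub, Clinical+KinSub, ...) and scored by
  Harrell's C-index on the held-out samples; variants are compared with
  two-sided Wilcoxon rank-sum tests. Per-feature univariate/multivariate
  Cox models (HR, 95% CI, Wald p) and median-split Kaplan–Meier curves
  with log-rank tests characterize individual biomarkers.
- **Enrichment** — hypergeometric over-representation of the selected
  genes (edges contribute both endpoints) against user-supplied GMT gene
  sets, Benjamini–Hochberg adjusted.
- **Synthetic cohorts** — a seeded generator with planted class-specific
  correlations, mean shifts, and Weibull proportional-hazards event times,
  so the whole pipeline is testable without access to patient data.

## Worked example

```r
library(edgekin)

spec <- demo_cohort_spec(seed = 7, n_per_class = 60, n_pairs = 10)
cohort <- simulate_cohort(spec)
cohort
#> ks_cohort: 20 genes x 120 samples, 10 network pair(s), 96 event(s)

expr  <- log2_zscore(cohort$expression, log2 = FALSE)  # already continuous
feats <- edge_transform(expr, cohort$network)
feats
#> ks_features: 20 node + 10 edge features x 120 samples (full params)

sel <- select_features(feats, alpha = 0.05, seed = 3)
sel
#> ks_selection: 5 prefilter survivor(s), 5 selected (1 node, 4 edge)
#> pooled out-of-fold AUC = 0.901 at lambda = 0.01714

km <- km_median_split(feats$values["KIN001-SUB001", ],
                      cohort$clinical$time, cohort$clinical$event)
km
#> ks_km: median split at -0.008964 (low n=60, high n=60)
#> log-rank chi-squared = 26.084, p = 3.268e-07
```

The cohort plants differential correlations (+0.6 / −0.6) on the first two
kinase–substrate pairs and drives the hazard through those edges
(log-hazard 1 per unit edge value). Selection recovers both planted edges
among its five features with an out-of-fold AUC of 0.90, and the
median-split Kaplan–Meier analysis of the first planted edge separates
high- from low-risk patients at p ≈ 3e−7: samples where kinase and
substrate deviate concordantly from their class means fail earlier.

The staged runner executes everything end to end with a manifest,
checksum-based resume, and byte-reproducible outputs:

```r
run_pipeline(pipeline_config("myrun", seed = 1))
```

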