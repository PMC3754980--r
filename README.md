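# mwaskit

Case–control metabolome-wide association analysis (MWAS) for untargeted
LC-MS feature tables, built for studies like a plasma comparison of
neovascular age-related macular degeneration patients against controls:
modest cohorts (tens of samples), one to two thousand m/z features, and no
deposited raw data — so the package ships a synthetic cohort generator with
ground truth that makes every stage testable end to end.

It is aimed at analysts who receive an apLCMS-style feature table (m/z,
retention time, per-sample ion intensity) plus sample metadata and want the
standard screening cascade with reproducible, inspectable intermediates.

## What it computes

1. **Cohort balance** — two-sided Fisher exact tests for categorical
   covariates and two-sided (Welch or pooled) t-tests for continuous ones,
   including a summary-statistics entry point so published mean ± SD values
   can be tested directly. The Fisher p-value is the point-probability sum
   `p = Σ { P(X = k) : P(X = k) ≤ P(X = a) }` over the hypergeometric
   support, computed via log-gamma.
2. **Univariate screen** — features present in < 50% of samples are
   excluded; each remaining feature gets a two-tailed t-test on the raw and
   on the log2 scale; Benjamini–Hochberg step-up FDR control is applied at
   q = 0.05 (raw) and q = 0.2 (log2); the intersection of the two
   significant lists and the direction of change are flagged, and
   Manhattan-plot data (m/z vs −log10 p) are exported.
3. **Ion clustering** — Pearson correlations between features
   (pairwise-complete, log2 scale); discriminatory features with any
   correlation at r > 0.81 are retained as seeds; connected components of
   seed–seed edges form clusters, seeds without seed–seed edges are
   "independent", and correlated satellite features are attached in rank
   order of r. Co-eluting adducts of one chemical correlate this strongly,
   so clusters approximate chemicals.
4. **Adduct annotation** — a feature of observed m/z matches a database
   record of neutral monoisotopic mass M when
   `|1e6 · (mz − (M + Δ)) / (M + Δ)| ≤ 10 ppm` for an adduct shift
   Δ ∈ {M+H, M+Na, M+K, M+H−H₂O, M+H+2H₂O}; masses come from a Hill-formula
   parser over monoisotopic element masses. Cluster-batch searches and a
   random-m/z background match rate are included.
5. **Multivariate panel** — OPLS-DA (Trygg–Wold orthogonal component
   removal, then NIPALS PLS), panel selection by variance-weighted squared
   predictive loadings (top 5%), shrinkage LDA classification, and a
   cross-validation engine (stratified 10-fold and leave-one-out) that keeps
   imputation, scaling and feature selection inside each training fold.
6. **Synthetic cohorts** — a generative model with latent per-chemical log2
   abundances, Dirichlet adduct efficiencies, ppm-scale m/z error,
   limit-of-detection censoring plus random dropout, and a ground-truth map
   used by `truth_recovery_report()` to score sensitivity/FDP, cluster
   agreement (adjusted Rand) and annotation top-hit accuracy.

## Worked example

```r
library(mwaskit)

sim <- simulate_dataset(simulation_config(seed = 1))   # 26 vs 19, 1680 features
filtered <- presence_filter(sim$table, 0.5)
res <- run_mwas(filtered, sim$samples, mwas_config())
sum(res$sig_raw); sum(res$sig_log2); sum(res$in_intersection)
#> 28, 146, 28

cm <- correlation_matrix(filtered)
cl <- build_clusters(res$feature_id[res$in_intersection], cm, filtered)
length(cl$clusters)       #> 10 clusters of co-varying ions
annotate_feature(448.303, read_metabolite_db(
  system.file("extdata", "metabolite_db_small.tsv", package = "mwaskit")))
#> glycocholic acid via M+H-H2O at -6.13 ppm
```

The same flow, with commentary and outputs on disk, is in the numbered
scripts under `analysis/` (run them in order from the repository root; they
write to `results/`). On the default synthetic cohort they print the
cascade 1680 → 1531 features, 28 raw / 146 log2 / 28 intersecting
significant features, ten recovered ion clusters (adjusted Rand 1.00
against the generating chemicals), 99% annotation top-hit accuracy, and a
77-feature OPLS-derived panel with perfect resubstitution and
cross-validated accuracy at the planted effect size.

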