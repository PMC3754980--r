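---
title: "Methods: case-control MWAS of LC-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control MWAS of LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwaskit)
```

# The problem

Untargeted positive-mode LC-MS profiling of plasma yields a table of m/z
features — each a (m/z, retention time) pair with an integrated ion
intensity per sample — on the order of 1,000–2,000 features for a
85–850 Da acquisition window. In a case-control design the questions are:
which features differ between groups, which groups of features are really
one chemical seen as several ions, what chemical identities are consistent
with the observed masses, and whether the profile as a whole separates the
groups. `mwaskit` implements that cascade for small discovery cohorts
(its reference configuration is 26 cases vs 19 controls), with every stage
exposed as a function so the workflow is scriptable and testable.

Three facts about such data shape the design. Intensities are roughly
log-normal with heavy censoring at the limit of detection, so zero from the
peak-extraction software means "not detected", not "absent at zero
abundance"; electrospray ionization emits several ions per chemical
(protonated, sodiated, water-loss, ... forms) whose intensities co-vary
strongly across samples; and mass accuracy is a few ppm, so identity
assignment is a tolerance search, not a lookup.

# Statistical procedures

## Presence filtering and dual-scale testing

Features detected in fewer than 50% of samples are removed before testing
(the threshold is configurable; the count is over all samples, not per
group). Each remaining feature is tested case-vs-control twice: on the raw
intensity scale and on log2 intensities. The default test is Welch's
two-tailed t-test — the variance of ion intensities routinely differs
between groups — with the pooled-variance variant available; published
summary statistics (mean, SD, n) can be tested through the same code path.
Missing values are excluded pairwise, never imputed, and a feature with
fewer than two present values in a group is marked untestable and excluded
from the multiple-testing denominator.

Both p-value vectors are corrected by the Benjamini–Hochberg step-up rule,
implemented directly (sort, reject up to the largest i with
p(i) ≤ i·q/m; adjusted values are the monotone minimum of p(i)·m/i capped
at 1). The two FDR levels default to q = 0.05 on the raw scale and
q = 0.2 on the log2 scale, and the intersection of the two rejection lists
is the primary discriminatory set: requiring significance on both scales
guards against single-scale artifacts (outliers drive raw-scale tests;
heavy censoring distorts log-scale tests). Rejection counts are
non-decreasing in q by construction, which the tests assert as a property
on arbitrary p-vectors.

## Cohort balance

Categorical covariates are compared by the two-sided Fisher exact test
under the point-probability convention: all tables with the observed
margins whose hypergeometric probability does not exceed the observed
table's (relative tie tolerance 1e-7) contribute to p. Point probabilities
are computed via `lchoose` on the log scale, so large cohorts cannot
overflow. A degenerate margin returns p = 1 with a warning. Continuous
covariates use the same t-test machinery as the feature screen.

## Ion clustering

Pearson correlations are computed between all filtered features with
pairwise-complete observations, on log2 intensities by default (the
correlation among ions of one chemical is multiplicative, hence linear
after log; the raw scale is available). Pairs sharing fewer than 10
samples, or involving a constant feature, are treated as missing rather
than reported at a meaningless value.

Cluster construction follows the rule that features derived from one
chemical correlate at r > 0.81 (strictly greater; an empirical instrument-
and protocol-level observation, not a fitted threshold). A discriminatory
feature with at least one correlation above threshold — to anything in the
filtered table — is a seed; clusters are connected components of seed–seed
edges; a seed whose only strong correlates are non-seeds is reported as
"independent". Connectivity is deliberately *not* extended through shared
satellites: two seeds correlated with the same third feature but not with
each other remain separate, because a satellite can be a background ion
correlated with two unrelated chemicals. One published cluster assignment
(a high-m/z feature grouped with a bile acid cluster despite no printed
seed–seed edge) is not reproducible under this rule; we keep the stricter
seed-edge definition and note the discrepancy rather than guessing an
undocumented rule. Satellites attach to a cluster ranked by decreasing r,
and output ordering is canonical (clusters by smallest seed m/z), so the
construction is invariant to input order.

## Adduct annotation

Neutral monoisotopic masses come from chemical formulas via a parser over
monoisotopic element masses (C 12 exactly, H 1.0078250319, N 14.0030740052,
O 15.9949146221, S 31.97207069, P 30.97376151, Na 22.98976928,
K 38.9637069, Cl 34.96885271 Da); a database record may instead carry a
mass directly, and when both are present they must agree within 1e-4 Da.
Five singly-charged positive-mode adducts are searched by default, with
electron-corrected cation masses:

| adduct     | shift (Da)   |
|------------|--------------|
| M+H        | +1.007276    |
| M+Na       | +22.989218   |
| M+K        | +38.963158   |
| M+H−H₂O    | −17.003289   |
| M+H+2H₂O   | +37.028406   |

The water-cluster form is interpreted as M+H plus two waters
(+36.021130 Da on top of the proton), symmetric to the water-loss form; it
is stated here prominently because the notation "H⁺(2H₂O)" is ambiguous in
parts of the literature. All ions are assumed singly charged, appropriate
for small molecules in an 85–850 Da window.

A hit is any (record, adduct) pair within the ppm tolerance, default 10 ppm
(the database search setting; 9 and 5 ppm are meaningful presets — the
pathway-database searches used 9 ppm and the instrument's nominal accuracy
is 5 ppm). The ppm error is signed, `1e6·(observed − theoretical)/
theoretical`; matching uses the absolute value and ties break by adduct
table order. `background_match_rate()` estimates the chance-match level by
drawing uniform m/z over the acquisition window — against dense public
databases roughly one random m/z in seven matches something, which is why
cluster-batch annotation (several correlated ions constraining one
chemical) is exposed as `annotate_cluster()`.

## OPLS-DA, panel selection, LDA, cross-validation

The multivariate stage autoscales features by default (unit variance is
the metabolomics convention for OPLS-DA; mean-centering alone is
available — a constant feature under autoscaling is an error, not a silent
drop). O-PLS follows the standard single-y recursion: the predictive weight
direction is `w ∝ X'y`; each orthogonal component takes the X-loading of
the current predictive score, removes its projection on `w`, normalizes,
and deflates X by the resulting score/loading pair; predictive components
are then extracted by NIPALS with y-deflation. One orthogonal and two
predictive components are the defaults. Per-component explained-variance
fractions are recorded against the total scaled sum of squares; scores are
mutually orthogonal to numerical precision and the fractions sum to at
most 1 — both asserted in tests.

"Top of the loadings" panel selection is operationalized as ranking
features by the sum over predictive components of squared loading weighted
by that component's variance fraction, keeping the top `ceil(0.05·p)` by
default, with deterministic tie-breaking by m/z. This is one reasonable
reading of a component-loading statistic that is not precisely defined in
the literature this package follows; the choice is recorded here and the
ranking function is small enough to swap.

Classification is two-class LDA with a pooled covariance shrunk toward
`mean(diag(S))·I` by a factor λ (λ = 0.5 automatically when features
approach or exceed samples, 0 when the covariance is comfortably
full-rank), equal class priors, and the Fisher rule. Kernel SVMs are not
implemented: the cross-validation engine takes any
`trainer(X_train, y_train) -> predict(X_new)` closure, so an external
classifier plugs in without touching the engine.

Cross-validation is stratified 10-fold (class ratios within one sample per
fold) or leave-one-out. The trainer runs entirely inside each training
fold — median imputation statistics, scaling, OPLS fitting and panel
selection included — so no test-fold information leaks into selection;
column-permutation invariance of the pooled CV accuracy is asserted as a
test. Missing values are median-imputed per feature for the multivariate
stage only; the univariate screen never imputes.

# The synthetic cohort generator

Because the reference study's raw tables are not deposited, validation is
against a generator whose defaults encode that study's conditions: 26
cases / 19 controls, 560 latent chemicals each emitting 3 adduct ions
(1680 features), m/z 85–850. Each chemical j has latent log2 abundance
`a_ji = μ_j + β_j·1[case] + ε`, ε ~ N(0, σ_between²), with μ_j ~ N(17, 2²)
(a typical ion-count scale), σ_between = 1, and β_j = ±1 log2 unit for a
10% differential fraction. Its adduct features add `log2(f_k) + η`,
η ~ N(0, σ_adduct²), where the ionization-efficiency vector f is a single
Dirichlet(2) draw per chemical — unequal but correlated ion intensities.
σ_adduct defaults to 0.2, which puts the median within-chemical Pearson r
above 0.81, i.e. exactly the regime the clustering rule assumes (asserted
by simulation in the tests). Observed m/z is the record's adduct m/z plus
N(0, (3 ppm)²) error — between the 5 ppm nominal accuracy and the ≤8 ppm
observed for standards. Missingness is censoring below the 10th percentile
of the pooled intensity distribution (not-at-random, as at a detection
limit) plus 5% uniform dropout. One seed drives the whole run;
regeneration is bit-identical.

What the generator does **not** emulate: retention-time drift and
alignment artifacts, isotope envelopes, correlated (biological) chemicals
— between-chemical correlation is zero by construction — multiplicative
batch effects, and heteroscedastic intensity-dependent noise. Passing
recovery tests therefore show the pipeline's inferential machinery is
correct under its own assumptions, not that those assumptions hold for any
particular instrument run.

# Numerical and design notes

- Zeros in input tables are coerced to missing by default (peak extractors
  emit 0 for "not detected"); a flag disables this for data with true
  zeros, and the log2 transform can apply an offset instead.
- Duplicate (m/z, rt) rows are rejected; duplicate m/z at distinct
  retention times are distinct features with `mz@rt` identifiers.
- Fisher ties use a 1e-7 relative tolerance on point probabilities,
  matching the dominant software convention.
- BH rejection flags come from the step-up definition, not from
  thresholding adjusted values; the two coincide and that equivalence is
  asserted rather than assumed.
- Correlations at exactly the clustering threshold are excluded (strict
  inequality).
- The analysis scripts run the workflow at the generator's study-scale
  defaults (1680 features × 45 samples); the test suite uses smaller
  configurations (tens to hundreds of chemicals, 50 replicates for the
  null-FDR study) chosen to exercise the same code paths at a few minutes
  of total runtime.

# Known limitations

Only two-group unadjusted comparisons are provided (no covariate models),
only singly-charged positive-mode adducts are searched, annotation is mass
matching — not identification; MS/MS or co-elution evidence is out of
scope — and the OPLS panel statistics on a 45-sample cohort are
descriptive: at this n, cross-validated accuracy has a binomial standard
error of about 0.07, which is why the label-permutation null is part of
the validation suite.
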