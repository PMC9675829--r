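---
title: "Methods: data-driven T2D subtyping, omics signatures, and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven T2D subtyping, omics signatures, and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dsubtypes)
```

## The model

Type 2 diabetes is clinically heterogeneous. A now widely replicated approach
stratifies T2D cases by k-means clustering of five clinical variables — age
at diabetes diagnosis, BMI, HbA1c, and the homeostasis-model indices of
beta-cell function (HOMA2-B) and insulin resistance (HOMA2-IR) — into four
subtypes: severe insulin-deficient (SIDD), severe insulin-resistant (SIRD),
mild obesity-related (MOD), and mild age-related (MARD) diabetes. Autoimmune
diabetes (SAID) is identified separately by rule (self-reported type 1
diabetes, or C-peptide < 0.5 nmol/L on insulin treatment) and excluded from
clustering. This package implements that workflow end to end, together with
the downstream omics and medication analyses that characterize the subtypes,
and a synthetic-cohort generator that makes every stage testable against a
known ground truth.

The clustering model is deliberately simple: all five variables are
standardized to mean 0, SD 1 on the fitting set, and k-means with many
restarts keeps the best-inertia solution. Cluster identity is assigned by
matching the center sign patterns to fixed prototypes (SIDD: high HbA1c, low
HOMA2-B; SIRD: high HOMA2-IR and BMI; MOD: high BMI, young onset; MARD: late
onset, small magnitudes elsewhere) via exhaustive one-to-one matching over
the 24 permutations, so labels are stable under any reordering of k-means
output. New subjects — a testing set, or an external cohort — are classified
by minimum Euclidean distance to the stored centers after applying the stored
standardization (the receiving cohort's own moments; see "Design choices").

## Choosing the number of clusters

`select_k()` combines two families of evidence, mirroring standard practice:

* **BIC over Gaussian mixtures** (via *mclust*, EM initialized by model-based
  hierarchical clustering), maximized over all covariance parameterizations
  per candidate `k`;
* **validity indices on k-means solutions**: mean silhouette width,
  Calinski-Harabasz (maximize), Davies-Bouldin (minimize), and the
  within-cluster-SS elbow, located as the largest second difference of the
  inertia curve (endpoints of the range cannot vote for the elbow criterion).

Each criterion casts one vote; the majority wins and ties break toward the
smaller `k`, preferring parsimony. Mixture models are used *only* for
selection; the final model is always k-means, so the fitted object is a set
of centroids, not a covariance-parameterized mixture.

## Stability and sensitivity diagnostics

**Clusterwise bootstrap Jaccard** (`jaccard_stability()`): rows are resampled
with replacement, k-means is refit, and each original cluster is scored by
its best Jaccard overlap (computed over the unique resampled subject ids)
with any new cluster; per-cluster means over re-runs above about 0.75 are
conventionally read as stable. The default is 500 re-runs, which bounds the
Monte-Carlo error of each per-cluster mean below about 0.01 while keeping the
procedure fast at cohort sizes of a few thousand.

**Fasting-state correction** (`correct_for_fasting()`): HOMA2 indices depend
on fasting state. Each index is regressed on self-reported minutes since the
last meal (over the T2D rows) and replaced by its residual plus the model
prediction at a reference of 480 minutes — the 8-hour convention used for
"fasting" laboratory values. If fasting time carries no information the
correction is a near-identity; if it is constant the regression is undefined
and the data pass through with a warning.

**Confounder sensitivity** (`confounder_sensitivity()`): candidate
confounders are tested against cluster membership (one-way ANOVA for
continuous, chi-square for categorical), the five clustering variables are
residualized on the significant ones, and the corrected data are
re-standardized and re-clustered. Reported are the assignment agreement with
the original partition (percent, after optimal label matching) and the ANOVA
p-value of each clustering variable across the corrected clusters.

**Partition agreement** (`compare_partitions()`): percent agreement is
maximized over one-to-one relabelings (exhaustive over the label
permutations), and the adjusted Rand index is computed from the contingency
table, so agreement numbers never depend on arbitrary cluster numbering.

## Case-control omics association

Protein and metabolite abundances are relative, not absolute, so all
statistics are built to be invariant under scaling and translation.
Preprocessing (`preprocess_features()`) drops features with more than 90%
missing entries, natural-log transforms (the base is immaterial after
standardization), z-scores per feature over observed values, and winsorizes
by clipping to ±5 SD. Missing entries remain missing and each feature's
model uses its complete cases; no imputation is attempted because the
missingness mechanism of such platforms is not identified.

Association models (`associate_case_control()`) follow the conventions of
the platforms: logistic regression of case status on the feature plus
covariates for proteins, linear regression of the feature on case status
plus covariates for metabolites; both report two-sided Wald p-values for the
feature term. Perfect separation in the logistic model is flagged (non-finite
estimate, missing p) rather than reported as a finite effect. Multiple
testing uses the conservative Bonferroni rule, `alpha / m` with `m` the
number of features tested on the platform. Replication
(`replication_concordance()`) restricts to primary-significant features
shared with the replication set, applies a Bonferroni threshold at the number
of shared features, and counts directional concordance of effect signs.

## Two-criteria subtype signatures

A feature is *subtype-specific* (`cluster_specific_features()`) iff

1. its mean in the subtype differs from all other subtypes combined at the
   Bonferroni level `alpha / m` (one-vs-rest linear model, no covariates;
   with a single binary predictor this Wald test is exactly the
   equal-variance two-sample t-test, which the test suite verifies), and
2. it differs from every other subtype individually at nominal p < 0.05.

The pairwise criterion is deliberately unadjusted — it acts as a veto against
calling a feature specific when two subtypes share the shift, not as an
inference in its own right. The Bonferroni denominator is the number of
features on the platform (not features × clusters). SAID and control groups
are display-only: they appear in the normalized profiles
(`normalized_cluster_profiles()`, means divided by the reference subtype's
mean with ±1.96·SE intervals) but never enter the tests. A feature may in
principle satisfy specificity for two clusters in opposite directions; both
records are emitted. Clusters with fewer than two members have their tests
flagged missing and are excluded from other clusters' pairwise conjunctions
rather than silently failing them.

`pc_variance_explained()` quantifies how much of the omics-wide structure
aligns with the subtypes: PCA over the T2D samples (missing entries
mean-filled for the decomposition only), then per-component R² from
regressing scores on subtype indicators.

## Medication enrichment

Free-text drug entries are annotated against a packaged toy dictionary
(~40 molecules with ATC codes; a deliberately small, synthetic stand-in for a
full drug-repository export) by exact matching after normalization
(lower-casing, punctuation stripping, dosage-token removal). Fuzzy matching
is deliberately excluded to keep the mapping auditable. Enrichment uses the
Fisher exact test: the two-sided p-value is the probability-ordering
definition (sum of hypergeometric probabilities no larger than the observed
table's, with a 1 + 1e-7 relative guard against floating-point ties, the
convention of standard implementations), and the odds ratio is the
conditional MLE solved from the noncentral hypergeometric mean equation.
Scans run at the molecule, ATC-subgroup (3-character), or ATC-main-group
level; case-control scans carry a Bonferroni column, cluster-vs-rest calls
are read at the nominal 0.05 level.

## The synthetic cohort: what it emulates, and what it does not

The generator (`simulation_params()`, `generate_cohort()`,
`generate_omics()`, `generate_medications()`) defines the study conditions
for all recovery and calibration tests:

* **Clinical structure.** T2D cases are drawn from a four-component Gaussian
  mixture in standardized 5-variable space with the canonical center sign
  patterns and default subtype fractions 0.25 / 0.04 / 0.24 / 0.47
  (SIRD rare, MARD largest), then mapped to physical units by a fixed affine
  transform whose means and SDs are preset constants of plausible magnitude
  (e.g. HbA1c 7.5 ± 1.5%), not estimates from any real cohort. A SAID sliver
  (109/1160 of diabetes rows) satisfies the SAID rule by construction;
  controls satisfy all four control rules by construction. HOMA2 indices are
  emitted directly by the generator, so no downstream stage depends on the
  HOMA2 estimator's absolute calibration.
* **Within-cluster spread.** The default within-cluster SD is 0.3
  standardized units per variable. This is an idealized, strongly separated
  preset: it makes each subtype's centroid estimable to within the 0.15 band
  used in the generator's own recovery check (about three standard errors at
  the smallest default subtype) and gives near-perfect membership recovery.
  Real cohorts overlap far more — stability values near 1.0 and recovery
  above 95% on this preset validate the *machinery*, they do not promise such
  performance on real data.
* **Omics.** Log-normal baselines with unit log-SD; planted subtype-specific
  features (disjoint blocks per subtype, shift = Cohen's d on the log scale,
  alternating sign) and case-control features shifted in all diabetes rows;
  missing-at-random masking; independent technical covariates (cell-lysis
  proxy, collection week, fasting minutes, tube number). Real platform
  features are correlated and missingness is typically abundance-dependent;
  neither is emulated, and covariances within clinical clusters are diagonal
  because no within-cluster covariance structure is published.
* **Medications.** Per-drug, per-group Bernoulli usage with planted
  differential probabilities, rendered as free-text synonym variants with
  randomized case, punctuation, and dosage suffixes.

## Numerical choices and tie-breaks

* k-means: 100 restarts by default, best inertia kept; fits are
  deterministic given the seed. When `k` equals the number of rows the exact
  zero-inertia solution is returned directly.
* Nearest-center ties break toward the lowest cluster index — a
  measure-zero event where determinism matters more than the choice.
  Distances are computed per center from explicit differences (not the
  expanded quadratic form), so a point at a center is at distance exactly 0
  and symmetric ties are exact.
* `select_k` vote ties break toward the smaller `k`.
* Standardization refuses zero-variance columns by name; preprocessing
  converts non-positive abundances to missing with a warning (they cannot be
  log-scaled) and reports every excluded feature in its log.
* Glucose in mg/dL is converted to mmol/L by division by 18.016 at the HOMA2
  boundary; clinical tables keep mg/dL.
* The default HOMA2 estimator is a documented monotone parametric
  approximation, `HOMA2-B = 100 (c/0.55) (5 - 2.5)/(g - 2.5)` and
  `HOMA2-IR = g c / (5 × 0.55)`, calibrated so the reference input
  (5.0 mmol/L, 0.55 nmol/L) maps to (100%, 1.0), with inputs clamped to
  glucose 3.5–25 mmol/L and C-peptide 0.2–3.5 nmol/L and flagged. The
  published homeostasis computer model is not open source; because the
  estimator is pluggable and the generator emits HOMA2 directly, no test or
  analysis depends on the approximation's absolute values.
* Per-stage pipeline seeds are derived from the master seed by fixed small
  offsets, so single stages can be re-run in isolation and reproduce their
  outputs.

## Design choices where the design was open

* **Transfer convention.** When classifying a cohort with external centers,
  the receiving cohort's own standardization moments are used. Center
  coordinates are exchanged in standardized units, and standardizing with
  the receiving cohort's moments is the only option that does not require
  shipping the donor cohort's raw moments alongside the centers.
* **Diabetes-rule precedence.** The prediabetes exclusion (HbA1c 5.7–6.4)
  applies only to subjects who do not meet any diabetes condition, so a
  diagnosed case with HbA1c 6.0 is T2D, not excluded. The gestational
  exclusion applies before everything except completeness.
* **Strict thresholds.** "Glucose > 200 mg/dL" and "HbA1c > 6.5%" are strict
  inequalities, as printed in the rule set.
* **Sex-specific sensitivity clustering** reuses the ordinary fit on sex
  subsets plus partition comparison; it needs no separate estimator.

## Problem sizes used in the checks

The packaged checks run the default preset at 1000 diabetes rows for
cluster-count voting (k = 2..15) and 500-re-run bootstrap stability; signature
recovery uses 420 cases with 1305 protein features and planted d = 2 effects;
calibration suites use 1000 null features (p-uniformity), 150 replicates of
200-feature families (family-wise error), and 1000 null drugs at 400 + 400
subjects (enrichment type-I). These sizes make every recovery and calibration
property measurable with comfortable margins while each suite completes in
minutes on a single CPU.

## Known limitations

* The generator's diagonal within-cluster covariance and independent omics
  features understate the redundancy of real platforms; power estimates on
  synthetic data are therefore optimistic.
* The two-criteria signature rule inherits the discreteness of its nominal
  pairwise vetoes: with very small clusters (such as SIRD at 4% of a small
  cohort) pairwise power, not the Bonferroni criterion, limits sensitivity.
* The toy drug dictionary covers ~40 molecules; real free-text medication
  data requires a full repository and still leaves unmatched strings, which
  the annotation step logs but does not resolve.
* Borderline-subject handling (cases nearly equidistant between centers) is
  not modeled; assignments are always hard.
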