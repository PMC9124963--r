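---
title: "Methods: platelet RNA diagnostic signatures with tepsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: platelet RNA diagnostic signatures with tepsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepsig)
```

## The problem

Tumor-educated platelets (TEPs) take up tumor-derived RNA in circulation,
so the platelet transcriptome of a cancer patient differs subtly from that
of a healthy donor. `tepsig` turns a raw gene-by-sample count matrix from
platelet RNA sequencing, plus a sample sheet (case/control class, training/
validation cohort, batch), into a compact cross-validated SVM gene
signature with a full diagnostic evaluation. The motivating application is
the detection of esophageal squamous cell carcinoma (ESCC) from peripheral
blood, but nothing in the pipeline is tumor-type specific.

The pipeline has seven statistical stages, each exposed as an exported
function and composed by `tep_fit()`:

1. **Low-count filtering** (`filter_low_count_genes`): a gene is dropped
   when it has fewer than `min_count = 5` reads in strictly more than
   `max_frac_below = 95%` of samples. The boundary is deliberately strict:
   detection in exactly 5% of samples retains the gene.
2. **Negative-control discovery** (`select_control_genes`): per-sample
   library sizes are the column sums of the *unfiltered* matrix; genes whose
   raw counts have Pearson correlation strictly above `control_r = 0.7`
   with library size are declared negative controls. The correlation is
   signed and computed on the raw scale: these are genes that track
   sequencing depth and are therefore assumed to carry technical but not
   disease variation.
3. **Batch adjustment** (`batch_adjust`): a per-gene location-scale
   adjustment in the ComBat family. For each gene a linear model with the
   class label as a protected covariate and batch as a nuisance term is
   fit; batch mean shifts are removed (up to their sample-weighted mean, so
   the gene's grand mean is preserved), within-batch residual scales are
   equalized to the pooled scale, and the class effect is re-added. We do
   **not** apply empirical-Bayes shrinkage across genes: the shrinkage-free
   estimator is fully specified, exactly testable (a single batch is the
   identity; a planted constant shift is removed to machine precision), and
   behaves almost identically at these sample sizes.
4. **Removal of unwanted variation** (`estimate_unwanted_factors`,
   `remove_unwanted_variation`): the RUVg idea. Writing the log2 expression
   as `Y = X beta + W alpha + eps`, the sample factors `W` are estimated
   from the row-centered control-gene submatrix by truncated SVD (right
   singular vectors scaled by singular values), gene loadings `alpha` by
   least squares for all genes, and `W alpha` is subtracted. Class labels
   are never consulted. The default is `k = 1` factor — the minimal choice,
   since the number of nuisance factors is not identifiable from first
   principles; the singular-value scree is stored in the fitted object for
   inspection, and `k` is a configuration field. Normalized values stay on
   the log2 scale for every downstream stage.
5. **Differential expression** (`run_diffexp`): per gene, a univariable
   logistic regression of the class label on normalized expression,
   `logit P(case) = b0 + b1 x`, with a Wald p-value, Benjamini-Hochberg
   adjustment across genes, and a fold change defined as the difference of
   class means on the log2 scale (`|FC| > 2` is `|log2fc| > 1`). Thresholds
   are strict inequalities. Perfect and quasi-perfect separation (including
   the Hauck-Donner regime, detected as a slope above 10 per standard
   deviation of expression) fall back to a Firth-type Jeffreys-penalized
   fit, flagged per gene. A raw-p selection mode (`de_raw_p`, e.g. 0.001)
   mirrors the looser selection used for enrichment-style analyses.
6. **mRMR feature ranking** (`rank_mrmr`): candidates are the significant
   genes, truncated to the `mrmr_pool = 200` smallest p-values. Relevance
   and redundancy are Gaussian mutual information computed from
   correlations, `MI = -1/2 ln(1 - rho^2)` (point-biserial against the
   class, Pearson between genes), which avoids the binning choices of
   discrete MI estimators and makes the ranking invariant to affine
   rescaling of any gene. The default scheme is MID
   (relevance − mean redundancy); MIQ is available. Ties are broken by
   ascending DE p-value and then gene identifier, so the ranking is fully
   deterministic.
7. **SVM with leave-one-out cross-validation** (`loocv_evaluate`,
   `fit_final`): a Gaussian-kernel soft-margin SVM over the grid
   gamma ∈ 10^(-10..1), cost ∈ 2^(1..10). For every left-out training
   sample, features are standardized on the remaining n−1 samples and
   `(gamma, cost)` are selected on that fold alone; the held-out sample is
   scored blind with the signed decision value. The modal fold choice
   becomes the frozen pair; the final model is refit on the whole training
   cohort and applied, with training-frozen centers and scales, to the
   validation cohort. The score cutoff maximizes the Youden index
   `J = sens + spec − 1` over midpoints of adjacent unique scores, ties
   resolved toward the lower cutoff (higher sensitivity).

Evaluation (`classifier_report`) reports the confusion matrix,
sensitivity, specificity, accuracy, Matthews correlation coefficient,
Youden index, the tie-grouped trapezoidal ROC (whose area equals the
Mann-Whitney statistic), and a stratified bootstrap percentile confidence
interval for the AUC (`n_boot = 2000`; DeLong-style analytic intervals are
deliberately not implemented — the bootstrap is assumption-light and
deterministic given a seed). Rates are conventionally printed to three
decimals, percentages to one.

## Design choices in ambiguous territory

Several details are not determined by the problem statement; we fixed them
as follows and treat them as part of the method definition:

* **Kernel**: Gaussian. A tuned `gamma` only makes sense for RBF-family
  kernels.
* **Prediction score**: the signed decision value (distance to the
  hyperplane), not a calibrated probability — deterministic and monotone in
  the margin.
* **Inner hyperparameter selection**: stratified 5-fold cross-validated
  accuracy inside each LOOCV training fold. Resubstitution accuracy would
  saturate at 1 over most of a grid this large and make the selection
  meaningless; ties go to smaller cost, then smaller gamma (the simplest
  model), which also fixes the grid order. Note that on label-free (null)
  data, leave-one-out evaluation of any regularized classifier is
  anti-biased below chance — a weak fold model leans toward the training
  fold's majority class, which on balanced data is systematically the
  held-out sample's opposite — so null cross-validation levels are best
  estimated by averaging over label permutations.
* **Feature scope of DE**: univariable, no clinical covariates; unwanted
  variation has already been removed by subtraction rather than entering
  the per-gene model as covariates.
* **Signature size**: fixed at 3 by default (`signature_size = 3`), the
  size of a practical qPCR-verifiable panel; `signature_size = "auto"` instead picks the
  smallest size whose LOOCV accuracy is within `signature_delta = 0.02` of
  the best over `1:signature_max`.
* **mRMR placement**: the ranking is computed once on the full training
  cohort, before LOOCV, as the original workflow implies. This leaks
  selection information into the training-cohort LOOCV estimate (a known
  property of non-nested selection); the validation-cohort evaluation is
  untouched by it, which is why the validation report is the one to trust.
  Consequently the package never quotes a training-cohort AUC for null
  data: on a null study the DE thresholds select nothing and `tep_fit()`
  refuses to build a signature, which is the correct type-I behavior.
* **Validation cutoff**: the report carries both the training-derived
  cutoff applied blind to the validation scores and a cutoff re-optimized
  on the validation cohort, labelled `cutoff_source = "training-derived"` /
  `"validation-optimized"`. Re-optimizing on validation flatters the
  operating point; surfacing both makes the ambiguity explicit instead of
  hiding it.

## The synthetic-data generator

Real platelet count data cannot ship with the package, so
`simulate_study()` generates studies with known ground truth. Counts are
negative binomial around

```
mu_ij = L_j * b_i * 2^(s_i * fc_i * c_j) * exp(batch_(b(j),i) + lambda_i * w_j)
```

* `L_j ~ LogNormal(0, 0.5)`: per-sample library-size factors.
* `b_i`: baselines. Background genes are heavy-tailed
  (`LogNormal(log 20, 1.5)`), matching the dominance of a few transcripts
  in platelet RNA; housekeeping genes sit high (`LogNormal(log 500, 0.5)`);
  planted signature genes are moderately expressed
  (`LogNormal(log 50, 0.8)`) — a diagnostic biomarker near the detection
  limit would test the filter, not the statistics.
* `c_j` is the class indicator and `fc_i = log2_fc = 1.5` for the `n_de =
  30` planted genes (70% up in cases), 0 otherwise.
* Batch offsets are per-gene, per-batch normal with SD 0.2 on the log
  scale; two batches by default, assigned stratified by class.
* `w_j` is the latent technical factor. By default it is **depth-linked**:
  the standardized log library-size factor, modelling a common upstream
  cause — platelet RNA yield and quality — that drives both sequencing
  depth and gene-specific responses. This mirrors the RUVg premise:
  negative control genes must be exposed to the unwanted variation while
  untouched by the disease, and in platelet data the dominant technical
  axis is exactly depth/input quality (platelet RNA yield itself differs
  between patient groups). `lambda_i ~ N(0, 0.5)` on 30% of
  non-housekeeping genes adds per-gene departures from proportional depth
  response. An `uv_mode = "independent"` switch makes `w` standard normal
  instead, and `uv_confound` shifts log depth by class — the stress test in
  which depth masquerades as disease signal and factor removal must rescue
  differential expression.
* Dispersion is tiered: housekeeping genes are technically noisy only
  (`size = 20`), background genes carry biological variation
  (`size = 1`, i.e. squared biological CV of about 1), planted genes sit
  between (`size = 2`). The tiering is what makes the generator
  faithful to the discovery problem: only housekeeping-like genes track
  depth tightly enough to pass the r > 0.7 control screen, while planted
  genes are detectable but not trivially separable.

Everything is a deterministic function of the configuration, including the
seed, and `write_study()` emits the same TSV formats the readers accept
plus a `truth.tsv` of per-gene roles.

**What the generator does not emulate:** sequence-level artifacts (GC and
fragment bias, mapping multi-hits), count correlation between co-regulated
genes (genes are conditionally independent given the factors), clinical
covariate structure beyond simple class shifts, and cohort drift between
training and validation. A pipeline that passes the synthetic recovery
checks is known to implement its statistics correctly; that is necessary,
not sufficient, for performance on real platelet data.

## Numerical conventions

* Strict inequalities at every selection threshold (r > 0.7, p_adj < 0.05,
  |log2fc| > 1); a gene exactly at a boundary is excluded.
* Pseudocount 1 before log2.
* Constant genes: excluded from control discovery and mRMR with a warning;
  a constant feature inside a CV fold gets scale 1 with a warning; a
  constant expression vector in a per-gene model returns slope 0, p = 1.
* Mutual information at |rho| = 1 is capped at −½ ln(1e−12).
* Exact ties in mRMR scores (tolerance 1e−12) resolve by DE p-value then
  gene id; grid-accuracy ties resolve toward smaller cost then gamma;
  Youden ties toward the lower cutoff.
* All stochastic steps (fold assignment, bootstrap) derive their streams
  from explicit seeds and restore the caller's RNG state.

## Problem sizes used in the shipped checks

The package's own test suite regenerates everything it tests. Unit tests
use compact studies (60-120 samples, 400-600 genes) with a reduced SVM
grid; the recovery checks use the default study conditions (80 samples,
2,000 genes, 100 housekeeping and 30 planted genes at log2 fold change
1.5) across 20 seeds, and the end-to-end run uses two cohorts of 80
samples with the full default grid. These sizes were chosen so that each
statistical claim is tested at the scale where its guarantee is stated
while a full run remains a desk-scale computation.

## Known limitations

* The training-cohort LOOCV estimate inherits optimism from non-nested
  feature selection (see above); rely on the validation cohort.
* Logistic Wald p-values saturate under strong separation; the Firth
  fallback bounds, but does not remove, this conservatism. With very strong
  planted effects the ranking of p-values remains valid while their
  absolute scale is conservative.
* The bootstrap AUC interval is percentile-based; with fewer than ~10
  samples per class its coverage degrades (a hard minimum of 5 per class is
  enforced).
* `batch_adjust` requires at least two samples per batch and silently
  relies on batches not being perfectly confounded with class.
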