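---
title: "Detecting group differences in seed-based infant functional connectivity"
author: "infantfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting group differences in seed-based infant functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantfc)
```

## The scientific problem

Resting-state fMRI measures spontaneous fluctuations of the BOLD signal;
the correlation between two regions' time courses (functional
connectivity, FC) indexes how tightly they are functionally coupled.
In cohorts of infants at familial risk of developmental dyslexia, the
question is whether the whole-brain FC *pattern* of specific
language- and reading-related regions already distinguishes at-risk
infants (group label "FHD": at least one first-degree relative with
dyslexia or reading difficulties) from controls — long before any
reading behaviour exists. Single connections are too noisy to carry such
a subtle group signal, so the unit of analysis is the multivariate FC
pattern of a seed region, and the statistic of interest is how well a
classifier separates the groups from it.

`infantfc` implements this analysis end to end: per-subject seed FC
patterns, a bootstrapped balanced linear-SVM classification with a
paired permutation null, family-wise-corrected seed selection, and
forward-model (Haufe) patterns for path-level interpretation — plus a
synthetic cohort generator that serves as its test bed.

## From time series to features

For each subject, the parcellated BOLD matrix (T frames x R regions,
optionally produced from voxel data by `aggregate_voxels()`) yields, for
a given seed region, the vector

z_j = atanh( cor(x_seed, x_j) ),  j over the R − 1 other regions,

computed by `seed_fc_pattern()`. The Fisher transformation stabilises
the variance of the correlation coefficient. Correlations are clamped to
|r| <= 1 − 1e-7 before `atanh` so that degenerate inputs (duplicated or
noise-free signals, which occur in synthetic data) stay finite instead
of poisoning the classifier. Negative correlations are retained as they
are; no thresholding or sign rule is applied. Atlas row order is the
single source of feature indexing: feature j of every weight or pattern
vector refers to the j-th non-seed region in atlas order
(`seed_feature_map()`).

Region identity is matched *by name* between a time-series file header
and the atlas, so files whose columns are stored in different orders are
read identically. The shipped default atlas (`default_atlas()`) is a
90-region AAL-style cerebral parcellation with 20 seed regions — 10
bilateral pairs covering the inferior frontal (orbital, triangular,
opercular), precentral, Heschl, inferior parietal, supramarginal,
angular, inferior temporal and fusiform cortices. The region count is
deliberately configurable (`synthetic_atlas()`): infant atlases derived
from adult parcellations differ in how many cerebral regions survive,
and nothing downstream depends on R = 90.

## The classification engine

One analysis tests one seed. Because the groups are unbalanced (the
reference design is 35 FHD vs 63 controls), each bootstrap iteration
(`run_iteration()`):

1. draws a random balanced subsample: all 35 FHD subjects plus 35
   controls drawn without replacement;
2. forms random FHD–control pairs and runs leave-one-pair-out
   cross-validation (LOPO): each fold holds out one subject per group,
   trains a linear soft-margin SVM (C = 1, no feature scaling) on the
   remaining 68, and classifies the held-out pair. Fold-aggregated
   accuracy, sensitivity (FHD recall) and specificity (control recall)
   are recorded;
3. permutes the group labels (preserving the 35/35 counts) and re-runs
   the identical CV procedure on the same subsample — pairing and folds
   re-derived from the permuted labels — giving the iteration's paired
   null metrics;
4. retrains on the full 70-subject sample to obtain the weight vector,
   and converts it to a forward-model activation pattern (below).

Repeating this `n_iterations` times (default 10,000;
`run_seed_classification()`) produces paired true and null metric
distributions, with the difference distribution diff_i = true_i −
null_i defined within iteration.

Design choices worth stating explicitly:

* **Pairing rule.** LOPO needs a pairing of FHD with control subjects;
  no covariate matching is used. Pairs are drawn uniformly at random and
  fresh in every iteration, so any effect of a particular matching
  averages out across iterations.
* **Null construction.** The permutation run repeats *the procedure*
  under permuted labels: the pairing/folds are rebuilt from the permuted
  labels. If instead the true-label folds are reused, training sets
  become class-imbalanced under permutation (a fold may hold out two
  same-labelled subjects), which biases null LOPO accuracy visibly below
  0.5 and would shift the whole difference distribution; rebuilding the
  folds keeps the null centred at chance, which is what a null is for.
  The control subsample *is* shared between the true and null runs, so
  the difference remains paired.
* **Ties.** A decision score of exactly zero classifies as control —
  deterministic and conservative toward the null.
* **Standardisation.** Off by default (the classifier is used with plain
  defaults); per-fold z-scoring is available via `standardize = TRUE`.
* **Covariates.** With `covariates = "age_months"` the features are
  residualised per fold on the training subjects only
  (`residualize_covariates()`); test rows are adjusted with training
  coefficients, so no information leaks across the fold boundary.
  A stratified 5-fold scheme (`cv_scheme = "kfold5"`) is available as a
  replication variant.
* **Determinism.** A master seed generates the per-iteration child seed
  vector up front, so iteration i is reproducible regardless of how
  many iterations run, in what order, or which seeds are processed
  first.

The SVM itself is the package's compiled SMO solver for the linear
C-SVC dual (second-order working-set selection, the conventional 1e-3
KKT tolerance, warm-started CV folds). The same surface can route
through LIBSVM via `engine = "e1071"`, and the test suite asserts
agreement between the two solvers to 1e-4 at tightened tolerance; the
in-package solver exists because the bootstrap loop performs millions of
small fits and per-call overhead dominates otherwise.

## Inference and seed selection

For each seed (`seed_inference()`):

* a one-sided paired t test across iterations asks whether the true
  distribution exceeds the null (`paired_t()`);
* a normal-approximation CI on the mean of the difference distribution,
  mean ± z(1+level)/2 · sd/sqrt(n) at level 0.99 (`diff_ci()`), must
  have a positive lower bound. This is a CI on the *mean true-minus-null
  difference*, and the reports label it as such: with 10,000 iterations
  an SD-based interval around a mean difference of ~0.05 would be an
  order of magnitude wider than the mean-CI, so the two must not be
  conflated;
* Cohen d = mean(diff)/sd(diff) (`cohen_d()`) must exceed 0.5 (a medium
  effect).

Because iterations are resamples of the same cohort rather than
independent observations, the paired t test (and the mean-CI) are
drastically anti-conservative when read alone — treating 10,000
resamples as 10,000 samples shrinks the standard error by a factor of
100. The selection rule is therefore always the **conjunction** of the
three criteria with a family-wise corrected p value; in practice the
Cohen-d threshold is the binding constraint on null data, and the
corrected p guards against a cohort whose accidental structure yields a
high raw accuracy.

The multiple-comparison correction across the n = 20 seed tests
(`correct_multiplicity()`) defaults to a Monte-Carlo max-statistic
correction: each seed's observed mean true accuracy is referred to the
empirical distribution of the per-iteration *maximum* null accuracy
across all tested seeds, with the add-one rule
p = (1 + #\{max-null >= observed\}) / (1 + n_iterations). Bonferroni and
Šidák adjustments are provided for sensitivity analysis. The corrected
p for a seed can never undercut the seed's own empirical p, and the
max-statistic construction controls the family-wise error in the
strong sense.

Cohort-level descriptives (`cohort_table()`) use the pooled-variance
Student t (df = n1 + n2 − 2 = 96 for 35 + 63 — matching the printed
df convention of such cohort tables) and an uncorrected Pearson
chi-squared for the sex table (a Yates-corrected value would not
reproduce the conventional printed statistic for these margins).

## Motion quality control

Framewise displacement (`framewise_displacement()`) follows the Power
convention: FD_t = sum of absolute frame-to-frame translation
differences plus the head radius (default 50 mm, configurable for
infant heads) times the absolute rotation differences; FD_1 = 0. Frames
with FD above `fd_threshold_mm` (default 0.5 mm) are flagged
(`flag_outliers()`), and each subject is summarised by outlier
percentage and mean FD after outlier removal — the two motion rows of a
standard cohort table. QC is reporting-only by default; with
`scrub = TRUE` flagged frames are additionally excluded from the FC
correlations. Intensity-based artifact criteria are not implemented;
only the motion trace is consulted.

## Haufe forward-model patterns

SVM weights are not interpretable path-by-path: a region can receive a
large weight because it suppresses noise, not because it carries the
group signal. The forward-model transformation a = Cov(X) w (Haufe et
al.'s equation; `haufe_pattern()`) converts each iteration's weight
vector into an activation pattern whose entries reflect how each FC
path covaries with the decision function. The covariance is taken over
the iteration's own 70-subject balanced sample — the same data that
produced the weights — and patterns are averaged unnormalised across
iterations (`mean_pattern` in the seed distributions). A per-iteration
scaling variant (dividing by the decision-score variance) exists in the
literature; the unnormalised form is used here and only the *relative*
pattern values across paths are interpreted.

As a univariate companion, `edge_group_t()` computes pooled two-sample
t statistics (FHD minus control, full unbalanced cohort, df = N − 2)
per path, and `pattern_t_correlation()` the Pearson correlation between
mean pattern values and t values across paths. On data where the group
difference is genuinely distributed over paths this correlation is
strongly positive even when no individual path survives testing — the
multivariate pattern aggregates what the univariate tests cannot see.
`rank_paths()` lists the most positive and most negative paths, ties
broken by atlas order.

## The synthetic cohort generator

No infant data ship with the package; `generate_cohort()` produces the
test bed. Per cohort:

* a block-structured baseline correlation matrix (`make_base_correlation()`,
  default R = 90 at reduced scale R = 30 in the validation runs, 6
  blocks, within-block correlation 0.3) stands in for a modular
  resting-state network structure;
* the FHD group's matrix is optionally perturbed by shifting the
  correlations between one seed and a set of target regions by `delta`
  (`inject_effect()`); after any perturbation or jitter the matrix is
  projected back to a valid correlation matrix by eigenvalue clipping
  (floor 1e-6) with diagonal renormalisation (`repair_correlation()`),
  and the *realised* post-repair shifts are stored in the cohort's
  provenance — all recovery checks compare against realised, not
  requested, deltas;
* each subject receives an individual matrix (population matrix plus
  symmetric jitter of SD `subject_sd` = 0.1 on the off-diagonals,
  repaired) and T = 120 i.i.d. zero-mean Gaussian frames from it;
* motion traces are random-walk drift (SD 0.017 mm per frame,
  rotational drift scaled by the head radius) plus transient spikes
  (probability 0.035/frame, amplitude 0.6 mm);
* ages are drawn from group means 8.9 and 8.3 months (SDs 2.4/2.3,
  truncated to 4–13) and sexes from group-specific proportions, so the
  demographic table exercises realistic, slightly imbalanced but
  non-significant group contrasts.

Where the defaults were genuinely open they were fixed once, on these
grounds: `subject_sd = 0.1` makes the between-subject z-variation
comparable to the T = 120 sampling noise of a Fisher-z value
(1/sqrt(T−3) ≈ 0.09), which puts null classification at chance while a
correlation shift of ~0.25 on a handful of paths is detected with a
large effect size — the qualitative regime of interest; the motion
parameters were chosen so that mean FD lands near 0.08 mm and outlier
percentages near 7%, the magnitudes typical of infant cohort tables.
Frames are i.i.d. (no temporal autocorrelation): the pipeline is
correlation-based and i.i.d. frames keep the generator's oracles exact;
an autocorrelated-BOLD extension would scale the effective T but not
change any estimand.

What passing tests on this generator do show: the engine is calibrated
(null accuracy at chance, type-I control of the full selection rule),
detects and localises planted seed-level effects, and its patterns
cohere with univariate effects. What they cannot show: robustness to
real BOLD artifacts (autocorrelation, scanner drift, registration
error), to atlas misfit, or to group differences in motion — real-data
claims need real data.

## Validation scale and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) runs the
full chain at a reduced but non-trivial scale chosen to exercise every
code path with tight Monte-Carlo error: cohorts of 35/63 subjects,
R = 30 regions, T = 120 frames, 5 seed regions, 250 iterations per
seed, 20 replicate null cohorts for the calibration study. At this
scale the grand-mean true-label accuracy over 100 null seed-tests lands
within [0.47, 0.53], the full selection rule fires on ≤3% of null
seed-tests, and an injected delta of −0.25 on 8 paths is detected as
the unique selected seed with its targets recovered among the
top-|pattern| paths. A production run at 10,000 iterations and R = 90
changes runtime, not code paths.

Remaining numerical conventions: correlation clamping at 1 − 1e-7;
SMO KKT tolerance 1e-3 (tightened to 1e-8 in solver-parity tests);
eigenvalue floor 1e-6 in correlation repair; decision-score ties to
control; degenerate paired tests fall back to a sign convention
(zero differences give p = 0.5). Zero-variance time series, single-class
training sets, rank-deficient covariates and out-of-range correlation
shifts raise errors naming the offending region/subject rather than
propagating NaNs.

## Limitations

The paired t test across iterations inherits the resampling
anti-conservatism discussed above and is never used alone. The
max-statistic correction is one reasonable Monte-Carlo construction;
others (e.g. permutation of the full pipeline at the cohort level) are
stricter but computationally out of reach at 10,000 iterations. The
generator's Gaussian, stationary, motion-independent signals are a
deliberate simplification. Hyperparameter optimisation (nested CV) is
intentionally absent: the classifier is run with default settings, and
accuracy differences between groups — not maximal accuracy — are the
estimand.
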