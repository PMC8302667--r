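---
title: "Quantitative disease risk scores: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative disease risk scores: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdrisk)
```

This vignette is the package's own account of the statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, the numerical choices made where a formula underdetermines
an implementation, and what the synthetic-data experiments do and do not show
about real EHR data.

## The feature matrix

The raw input is a long table of code occurrences `(subject_id, phecode,
age)`. A phecode is *present* for a subject when it occurs at least
`min_occurrences = 2` times; the threshold guards against one-off
rule-out or miscoded diagnoses. Occurrences are counted per record, not per
distinct date: the two conventions differ only when the same code is entered
repeatedly at one visit, and counting records keeps the operation a pure
function of the input table. Absence of a phecode is not evidence of health —
it may simply mean the condition was never assessed — which is why subjects
on the roster with no qualifying codes are retained as all-zero rows rather
than dropped.

Columns are centered and scaled by the sample standard deviation
(`n - 1` denominator, the ordinary sampling convention). Zero-variance
columns cannot be scaled and are dropped and recorded in the fitted
statistics; test-set matrices are always standardized with the *training*
means and SDs so that scores for new subjects live on the training scale.

Healthcare utilization is measured as the number of distinct ages at
observation in a subject's history — a proxy for contact intensity that is
deliberately insensitive to how many codes were recorded per visit.

## PheRS

PheRS weights each phecode by its log inverse prevalence in a reference
cohort, `w_j = log(N / n_j)`, with the reference taken to be the training
controls. Rare codes get large weights on the theory that rare diagnoses are
more informative about disease in general; the weights know nothing about the
target disease, which is precisely the weakness the other two scores address.
A phecode absent from the entire reference (`n_j = 0`) is smoothed to
`n_j = 1` rather than dropped: test subjects may still carry it, and a finite
weight `log N` is the natural continuation of the formula.

## LPC

The LPC score is an eigenvalue-weighted sum of the leading principal
components of the phecode correlation matrix, with the component signs fixed
so that weakly labeled cases score above controls (an exact tie keeps the
positive sign — an arbitrary but deterministic convention). Because the PCs
are learned without labels, the method is almost unsupervised: the labels
enter only through `K + 1` binary sign decisions, which is why noisy "silver
standard" labels suffice.

Raw eigenvalues are used as the component weights (rather than eigenvalue
shares `lambda/sum(lambda)`): the two choices differ by a constant factor per
fit, so every rank-based metric (AUROC, AUPRC, Spearman, bin prevalence) is
identical between them, and raw eigenvalues keep the algebraic identity
`LPC_i = sum_j w_j x_ij` with `w = sum_k lambda_k s_k u_k` exact
(`effective_feature_weights()`).

### Choosing K with the Tracy-Widom test

The number of informative components is chosen by testing eigenvalues from
the top down. At each step the leading remaining eigenvalue is normalized
against the remaining spectrum (`L = p * lambda / sum(lambda_rest)`,
effective sample size `n - 1`), centered and scaled with the Johnstone
constants

```
mu    = (sqrt(n_eff - 1) + sqrt(p))^2
sigma = (sqrt(n_eff - 1) + sqrt(p)) * (1/sqrt(n_eff - 1) + 1/sqrt(p))^(1/3)
```

and compared with the Tracy-Widom (beta = 1) critical value at
`alpha = 0.05`. Testing stops at the first non-significant eigenvalue.

The TW1 distribution itself is evaluated through the Chiani shifted-gamma
approximation (shape 46.446, scale 0.18605, shift 9.84801), which is accurate
to about 1e-4 in CDF across the relevant range; the tests check it against
the published significance points (0.9793, 2.0234, 3.2724 at the 95th, 99th,
and 99.9th percentiles). Two behaviors are worth knowing: under a pure-noise
correlation matrix the sequential test rejects slightly *less* often than
`alpha` (correlation spectra are a bit more compressed than the covariance
spectra the asymptotics describe), and under a strong factor the
renormalization of the remaining spectrum inflates later statistics, so `K`
tends to run large on strongly structured data. Neither hurts the score: the
later components carry small eigenvalue weights.

If no eigenvalue is significant the fit falls back to `K = 1` with a warning
rather than returning an identically-zero score.

## PheNorm

PheNorm starts from the count of *case-defining* phecodes — the codes that
name the disease itself, which PheRS and LPC deliberately exclude from their
feature sets — and normalizes it by utilization:
`z = log(1 + x_code) - alpha log(1 + x_util)`.

The exponent `alpha` is chosen on a grid (default 0 to 2 in steps of 0.01) to
minimize the Kolmogorov-Smirnov distance between the empirical distribution
of `z` and a fitted two-component equal-variance Gaussian mixture, the
working model for "diseased vs not" conditional on true status. The EM fit
uses a deterministic quantile-based initialization (the two quartiles), up to
500 iterations, and a relative log-likelihood tolerance of 1e-8; grid points
where the EM degenerates are skipped with a warning.

A caution on identifiability: the KS objective distinguishes values of
`alpha` only insofar as misnormalization makes `z` look *less* like a
two-normal mixture. When the within-class spread of `z` is comparable to the
spread of `log(1 + x_util)`, a two-component mixture absorbs the residual
utilization term almost perfectly and the objective is nearly flat in
`alpha`. The package's recovery experiments therefore use sharply separated
classes (means 1 and 3.5, SD 0.25) against a widely dispersed utilization
distribution (negative binomial, size 0.7, mean 20), conditions under which
the planted `alpha = 1` is recovered to within one grid step (median over
replicates). On data where utilization varies little, `alpha` is weakly
identified — and also matters little.

The denoising step draws a bootstrap of `B = 1e5` rows, corrupts each entry
independently to its column mean with dropout rate `r = 0.3`, and regresses
the *uncorrupted* `z` on the corrupted matrix (which contains `z` itself as a
column) by ordinary least squares. `alpha` is selected once on the full
training set before the bootstrap, and the bootstrap is drawn once; both
orderings are deterministic given the seed. With `r = 0` the regression is an
exact self-fit (R² = 1, unit coefficient on the `z` column), a property the
tests assert. A singular cross-product after corruption falls back to a
minimal ridge (1e-8 on the diagonal) with a warning, keeping the pipeline
total. Scoring always uses the uncorrupted feature vector.

Candidate features enter PheNorm as the same standardized presence values the
other scores use; the case-defining codes are excluded from the candidates
because their information enters through the count `x_code`.

## Evaluation

AUROC uses the Mann-Whitney midrank formulation (ties count 1/2), checked in
the tests against exhaustive pair counting. AUPRC is the step-interpolated
average precision over unique thresholds; trapezoidal interpolation of
precision-recall curves is biased upward, and the two estimators differ
slightly on small data, so the choice is stated here. Spearman correlation
with ordinal staging uses midranks with the large-sample t approximation for
the p-value. Percentile-bin prevalence assigns subjects to `n_bins = 60`
nearly equal bins by score rank (ties broken by stable input order, so bin
sizes differ by at most one); unknown-status subjects are excluded unless
explicitly counted as non-cases. The weight-enrichment comparison is a
one-sided Wilcoxon rank-sum test (relevant > rest), exact when both groups
have at most 10 members and no ties, otherwise the tie-corrected normal
approximation.

## Phecode pre-selection by PRS

Given a polygenic risk score (computed as the weighted allele sum over
supplied variant weights on the log relative-risk scale), each phecode is
regressed on the standardized PRS by logistic regression, and phecodes with
Wald p below `1e-5` are retained. The Wald test was chosen over the
likelihood ratio for speed and because at `n` in the thousands the two are
indistinguishable; phecodes with zero or full prevalence are skipped
(separation leaves no information to test). An optional covariate hook is
provided; the default fit is unadjusted.

## Gene-based association of the scores

The null model regresses the score on covariates. Because the scores are
right-skewed, the default family is the inverse-Gaussian GLM; the log link is
used instead of the canonical `1/mu^2` for numerical stability. The response
is shifted to positive support (`s' = s - min(s) + 0.01 IQR`) *only when it
contains non-positive values*: shifting an already-positive response would
change the mean model and bias covariate estimates, and the package's
recovery tests hold only on the unshifted scale. Non-convergence falls back
to the Gaussian family with a warning. A null model whose residual variance
is numerically zero (e.g. a covariate equal to the score) is flagged, and all
score tests on it return p = 1 with a warning.

All component tests are GLM score tests built from the null-model working
residuals, so the null model is fitted once per gene set:

* **Burden**: 1-df chi-square test of the Beta(1,25)-weighted dosage sum.
  The Beta density weighting `w(maf) = 25 (1 - maf)^24` upweights rarer
  variants smoothly.
* **Dispersion**: the variance-component statistic
  `Q = sum_j (w_j g_j' r)^2`, with the mixture-of-chi-squares null
  distribution approximated by moment matching on the eigenvalues of the
  projected genotype covariance (Liu-Tang-Zhang). Moment matching is accurate
  in the moderate tail but can deviate below about `p = 1e-8`; exact
  inversion was not used, and extremely small dispersion p-values should be
  read as "very small" rather than to the digit.
* **Ultra-rare aggregate**: the unweighted per-subject carrier count of
  MAC < 5 variants, tested as a burden.
* **Single-variant** tests for every polymorphic variant in the common and
  rare partitions.

For one variant the burden, dispersion, and single-variant tests coincide
exactly (the tests assert this), which anchors the three implementations to
each other.

Partitions follow the frequency conventions: common/low-frequency MAF > 0.01
(the boundary value 0.01 is assigned here, since the strict inequalities
leave it unassigned), rare MAF < 0.01 with MAC >= 5, ultra-rare MAC < 5;
monomorphic variants are excluded. MAF and MAC are computed on the observed
calls of the analysis cohort after orienting dosages to the minor allele;
missing genotypes are mean-imputed per variant *after* the frequency
computation, so imputation never changes MAC. Functionally weighted rare
tests run on the variants flagged as qualifying (deleterious missense/LoF,
supplied as input) with the Beta weight multiplied by the supplied functional
weight.

Component p-values are combined with the aggregated Cauchy test,
`T = mean(tan((0.5 - p) pi))`, `p_comb = 0.5 - atan(T)/pi`, into `p_all`,
`p_common`, and `p_rare`. A component p of exactly 1 arises only from
degenerate partitions (no carriers, constant burden) and is a pole of the
tangent transform; such components are treated as empty and dropped from the
combinations, and `acat_combine()` itself falls back to the Bonferroni-style
bound `min(1, k min(p))` if handed an exact 1, mirroring reference
Cauchy-combination implementations. Inputs below 1e-15 are clipped.

Variant QC applies the GATK-style hard filters (SNVs: QD < 2, MQ < 40,
FS > 60, SOR > 3, MQRankSum < -12.5, ReadPosRankSum < -8; indels: QD < 2,
ReadPosRankSum < -20, FS > 200, SOR > 10), removing a variant when *any*
condition fails and treating absent metrics as passing — filters are
evidence of badness, and a missing annotation is no evidence. Multi-allelic
VCF records are split into biallelic variants before QC.

## The synthetic cohort generator

The generator emulates the statistical structure the methods assume — and
only that structure. A standard-normal latent liability `L` drives a block
of relevant phecodes through `logit P(present) = a_j + b_j L + c log(1+u)`;
noise phecodes share the utilization term but not the liability; weak labels
come from liability quantiles (top 20% cases, bottom 50% controls, the rest
unknown); ordinal severity stages cut the within-case liability at quartiles;
utilization is negative binomial (size 2, mean 8) and confounds presence with
strength `c = 0.3`, the confounding PheNorm exists to remove. Present
phecodes receive `2 + Poisson(1)` occurrence records so they always clear the
presence threshold, while a 2% rate of sub-threshold singleton records
exercises the `>= 2` rule. A synthetic PRS proxy correlated 0.5 with the
liability stands in for an external PRS so that pre-selection can be
exercised end to end. Genotypes are Hardy-Weinberg draws over a mixed MAF
spectrum (20% common, 60% rare, 20% ultra-rare by default); causal genes add
`effect x` (standardized Beta-weighted rare burden) to the score, with causal
variants restricted to true MAF <= 0.007 so sampling noise cannot push the
planted rare signal across the 0.01 partition boundary.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: real phecode hierarchies and their induced
correlation structure beyond a single factor, visit-level temporal dynamics
and coding-practice drift, linkage disequilibrium between variants,
population stratification (the genetic PCs the real analysis adjusts for are
here just exchangeable covariates), and label error correlated with
utilization. Results on synthetic cohorts demonstrate the machinery is
correct and calibrated, not that any particular clinical AUROC will be
attained.

## Problem sizes and runtime choices

The test suite and acceptance script run everything at desk scale, chosen so
the full suite completes in a few minutes on one CPU: robustness comparisons
use 20 replicates of n = 4000 cohorts with 20 relevant + 200 noise phecodes;
type-I-error calibration uses 2000 null replicates at n = 1000 under the
Gaussian family; ACAT uniformity uses 1e4 replicates; alpha recovery uses 50
replicates at n = 1000 on a 0.05-step grid; Tracy-Widom null/spike checks use
n = 2000, J = 50. PheNorm's default bootstrap `B = 1e5` is kept in the
acceptance run (it is a single OLS on a 1e5-row matrix) and reduced in unit
tests where only identities are being checked.

## Known limitations

* The dispersion p-value is a moment-matching approximation; below ~1e-8 it
  is order-of-magnitude accurate only.
* The sequential Tracy-Widom test over-counts components under strong
  factors; `K` should be read as an upper envelope of the informative rank.
* PheNorm's `alpha` is weakly identified when utilization varies little
  (see above).
* LPC component weights are fixed at the eigenvalues; supervised weighting
  (principal-component regression, partial least squares) would likely do
  better when labeled data exist, and is out of scope here.
* The inverse-Gaussian family requires a positive response; scores that are
  non-positive are shifted, which preserves ranks but makes the fitted
  covariate coefficients scale-dependent.
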