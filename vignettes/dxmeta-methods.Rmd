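---
title: "Logistic-regression diagnostic meta-analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logistic-regression diagnostic meta-analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxmeta)
```

## The problem

A candidate diagnostic biomarker — here chromogranin-A (CHGA), whose
expression falls in early-stage colon cancer — is observed in several
independent case/control expression cohorts, each too small and too
platform-specific to settle the question alone. The package implements the
classical two-stage answer: turn each cohort into a 2×2 diagnostic table by
classifying its own samples, then combine the tables by diagnostic
test accuracy (DTA) meta-analysis.

## Stage 1: per-study logistic classification

Within each study, expression of the candidate gene is the single covariate
of a logistic regression on case status, fitted by iteratively reweighted
least squares. Samples with fitted probability ≥ 0.5 are called "case";
cross-tabulating calls against truth gives TP, FP, FN, TN.

Choices a user should know about:

- **Threshold 0.5.** It is the value that turns a logistic fit into its
  canonical classifier; an alternative (e.g. prevalence) can be passed via
  `threshold` in `confusion_from_fit()` / `pipeline_config()`. Ties at
  exactly the threshold are called "case", deterministically.
- **Resubstitution.** The classifier is evaluated on its own training
  samples, because the published tables tabulate every sample of each
  cohort. Resubstitution estimates are optimistic relative to held-out
  evaluation; they are the right quantity for reproducing this design, not
  an unbiased estimate of field performance.
- **Complete separation.** With a strongly shifted marker the MLE diverges;
  the IRLS iteration cap (50) stops it. The confusion table — the only
  quantity consumed downstream — is invariant to the diverging magnitude,
  so no penalisation is applied. A constant covariate degenerates to the
  prevalence model (slope 0).

## Stage 2: pooling

**Proportions.** Pooled sensitivity and specificity are aggregate
proportions, Σ numerators / Σ denominators over the raw counts. This "add
the tables" convention is what classical DTA software computes and is the
only rule consistent with the published pooled values given the five CHGA
tables (inverse-variance logit pooling gives ≈ 0.91 for sensitivity).
Heterogeneity is Cochran's Q with study-specific binomial variances
pᵢ(1−pᵢ)/nᵢ and the aggregate p̂ as centre; the published software's exact
variance convention for proportions is not recoverable, so small
discrepancies in I² (a few percentage points) are expected and tolerated.
I² on *sensitivity* is the headline heterogeneity figure, with I² < 50%
read as small heterogeneity.

**Ratios.** PLR, NLR and DOR are pooled on the natural-log scale. The fixed
stage uses inverse-variance weights from delta-method variances; the
random-effects stage adds the DerSimonian–Laird moment estimate of τ² and
reweights by 1/(vᵢ + τ²). Q and I² always come from the fixed-weight stage.
Any table containing a zero cell has 0.5 added to all four cells before
ratio computation (proportions use raw counts); the perturbation is O(1/n).
95% intervals are normal approximations on the pooling scale,
exponentiated back.

## The summary ROC curve

The Moses–Littenberg model regresses D = logit(sens) − logit(1−spec)
(= ln DOR) on S = logit(sens) + logit(1−spec), a proxy for the positivity
threshold. Inverting D = a + bS gives the curve
TPR(FPR) = expit(a/(1−b) + logit(FPR)(1+b)/(1−b)); Q\*, the point where
sensitivity equals specificity, is expit(a/2) in closed form for any slope,
because S = 0 there.

Numerical and design choices:

- **Weighting.** Both equal weights and inverse-variance weights
  (1/var ln DOR) are implemented; *weighted is the default*. On the five
  CHGA tables the weighted fit is the one whose symmetric-curve summary
  (AUC 0.9361, Q\* 0.8725) reproduces the published pair (0.9370, 0.8736);
  the unweighted fit (0.9415, 0.8793) also lands within the reproduction
  band.
- **Degenerate slopes.** |b| ≥ 1 makes the inverted curve non-monotone. The
  CHGA fit itself has b ≈ −1.28 — five studies with strongly varying
  thresholds leave the slope poorly determined — so the model is flagged
  `degenerate` and its headline AUC/Q\* come from the symmetric curve
  (slope forced to 0 at the fitted intercept), which is also the default
  summary of classical DTA software and exactly the convention under which
  the published AUC/Q\* pair is internally consistent
  (0.9370 = symmetric AUC at a = 2·logit(0.8736)).
- **Integration.** AUC is trapezoidal on a uniform FPR grid (step 1e-4),
  endpoints handled by their limits; halving the step moves the value by
  < 1e-6. Full-range integration over (0,1) is the default, matching the
  headline style of reporting; a restricted window is available via
  `range`.
- **Boundary proportions.** Sensitivity or specificity of exactly 0/1
  should be prevented by the continuity correction; if one reaches the SROC
  stage it is clamped at logit ±36 with a warning.

## Preprocessing

Expression matrices are standardised to log2 scale when their maximum
exceeds 100 (a matrix of credible log2 intensities cannot reach that
value; the heuristic is overridable), using log2(x+1) so zeros stay
finite. Quantile normalisation then forces every sample onto the average
empirical distribution, with ties receiving the mean of the tied ranks'
row means (the `limma::normalizeQuantiles` convention, which the package
delegates to). Normalisation is per-study: studies enter the meta-analysis
independently, and nothing in the two-stage design requires cross-study
intensities to be comparable.

## The synthetic study set

`generate_chga_cohorts()` emulates the CHGA cohort structure: four GEO
colon-cancer series — GSE44076 (98 early-stage cases; 148 controls split
into 50 healthy and 98 adjacent-mucosa samples, analysed as two entries
sharing the case arm), GSE74602 (30/30), GSE10972 (24/24), GSE23878
(35/24) — 187 distinct cases and 226 distinct controls in five analysis
entries. Intensities are Gaussian on the log2 scale: the published
preprocessing works on log-scale data, and Gaussian-after-log is the
simplest model with that property (the source analysis never states a
distribution family; this is an explicit assumption of the generator, not
an inference). Defaults, chosen once:

- `baseline_sd = 1` log2 unit — a typical microarray within-gene spread;
- `marker_shift = -2.5` — under the equal-variance Gaussian model the
  expected resubstitution sensitivity and specificity are
  Φ(|shift|/(2σ)) = Φ(1.25) ≈ 0.89, the observed CHGA operating point, and
  classification error rates are visibly nonzero;
- study-specific baseline means (8, 7, 9, 6.5 log2 units) stand in for
  platform differences and force per-study, rather than pooled-sample,
  classification;
- one global seed fans out to per-study child seeds by fixed arithmetic,
  so adding a study never perturbs earlier ones, and identical spec + seed
  is bit-identical.

What the generator does *not* emulate: probe-level structure, batch
effects, missing values, heavy-tailed intensities, correlated noise genes.
Tests passing on this generator therefore certify the statistical engine —
recovery of generating operating points, type-I behaviour of null genes,
ranking power — not robustness to real microarray artefacts.

## Known limitations

- The Moses–Littenberg model is a fixed regression on transformed
  proportions; it ignores within-study binomial error in S and is known to
  be biased at small study counts. The hierarchical bivariate
  (Reitsma/HSROC) model is deliberately out of scope.
- Aggregate-proportion pooling ignores between-study weighting for the
  proportion indices (by design, to match the published convention).
- Similar-gene ranking averages per-study Pearson correlations without
  weighting; the published single-cohort computation is a special case,
  and the multi-study rule is an extension.
- Confidence bands for the SROC curve beyond the intercept's standard
  error are not computed.

## Problem sizes

The test suite and workflow run at the scale of the motivating analysis:
five cohorts of 48–196 samples, panels of ≤ 51 genes, and 100-replicate
simulation batches for the operating-point and ranking checks — sizes at
which the full suite completes in well under a minute per batch on a
laptop-class core.
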