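---
title: "Directed information flow in resting-state brain networks: methods"
author: "gcflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information flow in resting-state brain networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`gcflow` analyses directed (effective) connectivity among 52 regions of
interest (ROIs) grouped into six resting-state subsystems: the three
default-network (DN) subsystems — medial temporal lobe (MTL, 6 ROIs),
dorsomedial prefrontal (DM, 9), midline core (Core, 9) — the two
frontoparietal control subsystems (FPCNA, 11; FPCNB, 9) and the dorsal
attention network (DAN, 8). Input is one conditioned BOLD time-series
matrix per subject (timepoints x ROIs, TR in seconds) plus a two-group
design (NC controls vs AD patients). The pipeline estimates a directed
connectivity matrix per subject, reduces it to consensus connections,
summarises directed flow at the regional and inter-system level, follows
its temporal co-evolution in sliding windows, quantifies the regulatory
effect of FPCNA on functional couplings, and classifies the groups.

## The connectivity estimator

For an ordered ROI pair `x -> y` the package uses bivariate Granger
causality at VAR order `p` (default 1): `y_t` is regressed once on an
intercept and its own `p` lags (restricted model) and once with the `p`
lags of `x` added (full model), both by OLS over the common `T - p`
estimation rows. The magnitude is the Geweke log variance ratio

    F(x -> y) = ln( RSS_restricted / RSS_full )  >= 0   (nats).

The measure is nonnegative so that regional and inter-system sums are
well defined; a signed path coefficient would make the summed
information-flow statistics ill-posed. Numerically negative values
(possible at roundoff scale) are clipped to zero, and the diagonal is
identically zero. At order 1 all ordered pairs are computed in closed
form from three R x R cross-product matrices of the mean-centred
response and lag blocks; the unit tests pin this fast path to the
generic two-regression path, and that in turn to an independent `lm()`
oracle, at 1e-10. Model order is configurable; order 1 matches the
sampling rate of TR = 2 s data, and a longer order mainly costs
estimation rows on 190-sample series. `suggest_order()` offers a
BIC-based check on that default, and `gc_pair(signed = TRUE)` exposes a
signed variant (the magnitude carrying the cross-lag coefficient's sign)
for sensitivity analyses only — signed values must not enter the summed
IFS statistics, which are defined over nonnegative strengths.

Assumptions worth stating: covariance stationarity within the analysed
series, adequacy of a linear VAR at the chosen order, and equal sampling
across ROIs. Zero-variance (constant) series are rejected rather than
silently producing 0/0.

## Information-flow-strength (IFS) statistics

With networks fixed by the partition, each ROI `r` in network `N` gets
eight nonnegative indicators from the (optionally consensus-masked)
matrix `F`: `intra_in`, `intra_out` (flow from/to other ROIs of `N`),
`inter_in`, `inter_out` (flow from/to the other networks), and the four
sums `intra_in_out`, `inter_in_out`, `intra_inter_in`,
`intra_inter_out`. Two conservation laws follow by construction and are
asserted exactly (up to summation-order roundoff) in the tests: within
each network the summed inflow equals the summed outflow, and globally
the summed inter-network inflow, outflow, and the total of all 30
ordered inter-system sums agree.

Group comparisons use the pooled-variance Student t (df = n1 + n2 - 2),
matching the degrees of freedom a 27-vs-24 design reports; the statistic
is oriented AD minus NC so negative t means lower in patients. The
primary uncorrected threshold is p < 0.01; the 30 inter-system tests are
additionally controlled by Benjamini-Hochberg FDR at q = 0.05, and both
views are reported side by side. Correlation follow-ups (intra vs inter
flow of disrupted ROIs; forward vs feedback flow of a network pair) use
Pearson r with Fisher's z transform, and two independent correlations
are compared with the normal Z statistic
`(atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`. Correlation
p-values are reported uncorrected and flagged as such.

## Consensus connections

All R(R-1) = 2652 ordered-pair magnitudes form a feature vector per
subject. Inside a leave-one-out loop, features are ranked on the
training split by the F-score

    F = [ (m+ - m)^2 + (m- - m)^2 ] / ( v+ + v- )

(class means `m+`, `m-`, grand mean `m`, class sample variances). A
linear SVM (C = 1, features standardized by training-split statistics)
gives a LOOCV accuracy for each candidate count `k` of top-ranked
features; the chosen `k` is the smallest argmax of that curve rather
than a fixed constant, because the optimal count is a property of the
data at hand. The consensus set is the intersection over folds of each
fold's top-`k` list; connections outside it are set to exactly zero for
the network analyses. Ranking inside each fold never touches the
held-out subject; a global-ranking variant exists behind a flag for
comparison only. An empty intersection warns instead of failing: it is a
legitimate outcome on weakly separated data.

## Sliding-window co-evolution

Windows are half-open sample ranges of `round(60 s / TR)` samples (30 at
TR = 2 s), shifted by 3 samples; at T = 190 this gives 54 windows with
last start 159. Within each window the same GC estimator runs on the
window's rows (re-centred by the regression intercept; the series is not
re-filtered per window, since filtering is a whole-series operation),
and the cross-network pair magnitudes of an ordered network pair are
averaged — by default over the consensus-masked pairs, for consistency
with the static analysis; in simulator studies the planted edge set
plays that role, since consensus selection needs a two-group cohort.
Per subject, the co-evolution of two inter-system interactions (for
example FPCNA->Core with Core->DAN) is the Pearson correlation of their
windowed series, Fisher-z transformed. One-sample t-tests per group ask
whether co-evolution is reliably nonzero; a pooled two-sample t compares
groups. Windowed estimates on 30 samples are individually noisy; the
design relies on averaging over selected pairs and correlating across
54 windows, and the simulator study (below) shows this suffices for a
modulation that is slow relative to the window.

## FPCNA regulation

For five functional-connectivity blocks (within-Core, within-MTL,
within-DM, Core-DAN, DM-DAN) the full strength is the sum over the
block's unordered ROI pairs of Fisher-z-transformed Pearson
correlations, each pair counted once. The partial strength recomputes
this after every block ROI's series is replaced by its OLS residual
against an intercept plus all FPCNA ROI series — residualization against
the full regressor set, equivalent to the block-partial correlation (the
tests pin it to the precision-matrix form at 1e-8). The regulatory
effect is `full - partial`; z-transforms are applied per pair before
summing. Paired t-tests ask whether removal changes a block within each
group; the two-sample t on the per-subject effects compares groups. A
rank-deficient FPCNA regressor set drops the dependent columns with a
warning; an empty removed network leaves the strength exactly unchanged.

## Classification

Single-indicator linear-SVM classification (C = 1) under LOOCV, with AD
as the positive class: accuracy, sensitivity, specificity from the
aggregated confusion counts, AUC from held-out decision values in the
Mann-Whitney form (ties count half). Decision values are re-oriented to
the positive class per fold because the underlying solver orients its
decision function by the order in which classes appear in the training
data. Significance comes from re-running the complete LOOCV under
`n_perm` label permutations (default 1000) with the add-one estimator
`p = (1 + #{permuted accuracy >= observed}) / (1 + n_perm)`: a
permutation p of exactly zero is not a valid estimate, so the smallest
reportable value is `1/(1 + n_perm)`. Because LOOCV accuracy is a
discrete statistic, permuted accuracies tie with the observed one in a
non-negligible fraction of permutations and the estimator is
deliberately conservative (valid, but stochastically larger than
uniform under the null); this is a property of any tie-inclusive
permutation p-value, not an implementation artifact.

## The synthetic-data generator

Because no subject-level data are distributable, validation runs on
block-structured VAR(1) cohorts with known coupling. The default
conditions mirror the reference study design: 27 NC and 24 AD subjects,
52 ROIs, 190 timepoints at TR = 2 s. Self-decay diagonals are drawn
uniformly from [0.25, 0.45]; within-network directed couplings appear
with probability 0.30 at strength 0.30 (random sign); cross-network
couplings with probability 0.04 at strength 0.40; matrices are shrunk
toward their diagonal until the spectral radius is at most 0.9, and each
subject discards a 200-sample burn-in. The AD scenario multiplies every
coupling incident to a DN ROI (MTL, DM or Core at either end) by the
attenuation factor (default 0.5), a one-parameter version of the
headline group contrast. The co-evolution scenario modulates two
disjoint chains of planted cross-network couplings (FPCNA->Core and
Core->DAN, four edges each at strength 0.35) by slow envelopes —
a 0.005 Hz sinusoid with random phase plus 50-s-smoothed noise, clipped
to [0.2, 1.8] — shared across the two chains for NC subjects and drawn
independently for AD subjects. A planted common driver (one FPCNA ROI's
series added at a chosen gain onto target ROIs) exercises the
regulation analysis; its closed-form prediction (`x = d + e1`,
`y = d + e2` with unit variances gives full r = 0.5, partial r = 0,
effect atanh 0.5) anchors the tests.

What the generator does not emulate: hemodynamic convolution (an
optional smoothing kernel exists but is off, because the analysis
operates on filtered BOLD directly and convolution would confound
desk-scale estimator validation), spatial structure below the ROI
level, motion and physiological artifacts, and non-Gaussian innovations.
Passing recovery tests therefore demonstrates correctness of the
estimator chain under the stated generative model, not robustness to
everything real fMRI contains.

## Numerical and design choices

* **Filtering.** The temporal bandpass (0.01-0.08 Hz) defaults to an
  ideal zero-phase spectral projection (mean removal, FFT, zeroing of
  out-of-band bins), the approach of widely used resting-state
  toolchains. It is exactly linear and idempotent, which the property
  tests exploit. A forward-backward Butterworth (order 2, reflective
  padding of about one low-frequency period) is available via
  `filter_method = "butterworth"`; it was not made the default because
  no realizable IIR magnitude response is even approximately idempotent
  on broadband input — refiltering keeps eroding the transition band by
  10-20% RMS regardless of order.
* **Order of conditioning.** Confound regression precedes filtering,
  and both precede everything else.
* **Timepoint count.** The reference acquisition is ambiguous between
  190 and 155 retained volumes; the generator and defaults use 190 and
  the count is configurable rather than resolved.
* **Residual variance convention.** Both GC regressions share the
  estimation-row count, so the variance denominator cancels in the
  ratio; tests can therefore use plain RSS ratios.
* **Ties.** F-score rank ties break by feature position (stable);
  AUC ties count one half; the accuracy-vs-k argmax takes the smallest
  k.
* **Degenerate inputs.** Constant series, rank-deficient designs,
  single-class folds, |r| = 1 in the Z test, and windows shorter than
  the estimator needs all raise classed errors (`gcflow_*`), except
  where a cohort-level run can continue meaningfully (a degenerate ROI
  in the correlation follow-up yields NA; an empty consensus warns).
* **Problem sizes in the validation suite.** The recovery studies run at
  the design's cohort geometry (27 vs 24, T = 190) with 100 replicates
  for the group-contrast study, 20 cohort averages for edge recovery,
  50 replicates per co-evolution scenario (6 subjects each), and a
  200-run permutation-calibration study at n = 20 subjects, d = 3
  features, 199 permutations — sizes chosen so the full suite stays
  desk-scale while keeping each test's Monte-Carlo error well inside
  its margin.

## Known limitations

Bivariate GC does not distinguish direct from mediated influence and is
sensitive to unmodelled hemodynamic lag differences; the consensus step
selects for discriminative, not necessarily strong, connections; the
30-sample windows make single-window estimates noisy by construction;
and the permutation p-value's conservatism under ties means its null
distribution sits above uniform (see the classification section). The
pipeline starts at ROI time series: image-space preprocessing is out of
scope.

## Reproducing a run

```{r, eval = FALSE}
library(gcflow)
part <- default_partition()
cohort <- simulate_cohort(part, seed = 1)        # 27 NC vs 24 AD
report <- run_pipeline(cohort, part,
                       run_config(rng_seed = 1, n_permutations = 1000),
                       out_dir = "gcflow_out")
summary(report)
```

Identical configuration and seed reproduce every output table byte for
byte.
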