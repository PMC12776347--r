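---
title: "Methods: k-means + classified mixed model prediction of DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-means + classified mixed model prediction of DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA methylation measurements are noisy, and cohorts are small — especially
for racial groups underrepresented in public genomic databases.  This
package predicts the *denoised* methylation of a patient, their true mixed
effect, from genetic (copy-number alteration, CNA) and clinical covariates,
by borrowing strength from other patients — across cancer types and racial
groups — whose methylation profiles look similar.

## Model and prediction rule

Patients are clustered on their full methylation profile; the cluster then
enters every per-outcome model as a random intercept.  For methylation
outcome $m$ and patient $i$ in cluster $j_i$:

$$y_{im} = x_i \beta_m + \alpha_{j_i m} + \epsilon_{im} = \theta_{im} + \epsilon_{im},
\qquad \alpha_{jm} \sim N(0, G_m),\ \epsilon_{im} \sim N(0, R_m),$$

where $x_i$ holds the CNA values, race, age, sex, stage and cancer type.
The prediction target is the mixed effect
$\theta_{im} = x_i\beta_m + \alpha_{j_i m}$: the patient's expected
methylation given covariates and cluster, free of measurement error.

A new (test) observation arrives with both $y_{nm}$ and $x_n$ but an unknown
cluster.  Classified mixed model prediction (CMMP), in its matched form with
each test observation its own group of size one, assigns the cluster whose
BLUP best explains the observed residual,

$$\hat I_m = \arg\min_j \big(y_{nm} - x_n\hat\beta_m - \hat\alpha_{jm}\big)^2,
\qquad \hat\theta_{nm} = x_n \hat\beta_m + \hat\alpha_{\hat I_m m},$$

with ties going to the lowest cluster index.  $\hat I_m$ is chosen
independently per outcome; the per-sample "consensus" cluster (the modal
$\hat I_m$ over outcomes) is reported for interpretation only and never
feeds back into predictions.  The competing predictors used throughout the
evaluation harness are the naive estimate ($\hat\theta = y_{nm}$ itself,
whose expected squared error is exactly the error variance $R_m$),
regression prediction ($x_n\hat\beta^{OLS}_m$), and oracle CMMP (the same
machinery fitted on the *true* training clusters, available only in
simulation, which approximately lower-bounds the k-means version).

## Estimation choices

**REML by 1-D profiling.**  Each outcome is fitted independently.  Writing
$\gamma = G/R$, the restricted likelihood is profiled so that only
$\log\gamma$ remains, optimized on $[-12, 12]$ with `stats::optimize`
(tolerance $10^{-8}$).  All cluster algebra uses the Woodbury identity —
$V_0^{-1} = I - \sum_j \tfrac{\gamma}{1 + n_j\gamma} J_j$ — so a fit costs
$O(np + p^2 k + p^3)$ per criterion evaluation and no $n \times n$ matrix is
ever formed.  The boundary $\hat G = 0$ is explicitly compared against the
interior optimum and returned when it wins, in which case the fit is exactly
OLS; a single cluster pins $\hat G = 0$ (it is confounded with the
intercept).  REML rather than ML keeps variance components approximately
unbiased, which the parametric bootstrap relies on.  BLUPs are the shrunken
cluster-mean residuals
$\hat\alpha_j = \tfrac{n_j\gamma}{1+n_j\gamma}\,\bar r_j$; with an intercept
in the design the *unweighted* sum $\sum_j \hat\alpha_j$ vanishes (the
$n_j$-weighted sum does so only in balanced designs).  The implementation is
cross-checked in the test suite against `lme4::lmer` and against a dense
grid-search REML oracle on small instances.

**Design encoding.**  Reference-cell coding with the alphabetically first
level as reference; the encoding map is stored at fit time and reused at
prediction, and an unseen level is an error rather than a silent drop.  Age
enters in decades (years / 10): with per-coefficient effect variance fixed
at .03 in the generator, raw years would let age dominate
$\mathrm{Var}(X\beta)$ and push the signal-to-noise ratio far above what is
realistic for methylation (SNR here is defined as
$\mathrm{Var}(X\hat\beta)/\hat\sigma^2$); decades keep each covariate's
contribution comparable.

**Number of clusters.**  `gap_statistic()` computes Tibshirani's gap with
B = 50 uniform reference datasets over each feature's observed range
(`cluster::clusGap`, `spaceH0 = "original"`), the $\sqrt{1 + 1/B}$ standard
error, and the `firstSEmax` selection rule — the smallest k whose gap is
within one SE of the first local maximum — which operationalizes "a high
gap value but not too many clusters".  A global-max rule is selectable.
k-means itself is `stats::kmeans` (Hartigan–Wong) with 10 seeded restarts
and 300 iterations; the trivial partitions $k = 1$ and $k = n$ are returned
in closed form.

## The parametric bootstrap

For real data $\theta_{nm}$ is unobservable, so the MSE of $\hat\theta_{nm}$
is estimated by parametric bootstrap: draw $k$ intercepts from
$N(0, \hat G_m)$, regenerate training outcomes from the fitted fixed
effects with errors $N(0, \hat R_m)$, regenerate each test outcome with the
intercept of its originally assigned cluster $\hat I_m$, refit the mixed
model (same training labels — k is not re-selected), rerun CMMP, and
average squared deviations over replicates.  Two targets are implemented:

* `as_written` (default): deviations from the original prediction
  $\hat\theta_{nm}$.  This measures predictor variability around the
  original fit.
* `bootstrap_truth`: deviations from the replicate's own true mixed effect
  $x_n\hat\beta_m + \alpha^b_{\hat I_m}$.  This is the conventional
  definition of a bootstrap MSPE, and it is the variant that calibrates
  against directly simulated MSE (the test suite checks agreement within
  25% at B = 100).

Both are kept because the boxed algorithm the default follows is ambiguous
on this point; the choice is a flag, not a fork.

## What the synthetic cohort emulates

`generate_dataset()` reproduces the *structure* of a pan-cancer
(cervical + lung adenocarcinoma) TCGA-like cohort, not its inaccessible
empirical marginals.  Defaults, each overridable via
`simulation_config()` / `default_covariate_distributions()`:

* n = 655 patients, P(CESC) = 254/655, all CESC patients female; LUAD
  patients female with probability .55.
* White fraction `bias` b, default .78 (the TCGA-like value; .681 would be
  population-representative); exactly `round(b n)` White rows
  (round-half-even), the rest drawn from a renormalized non-White table
  (Black .32, Asian .53, AI/AN .09, NHPI .06).
* 65 CNA covariates, iid on $\{-2,\dots,2\}$ with probabilities
  (.05, .15, .60, .15, .05); stage I–IV at (.45, .25, .20, .10); age
  truncated-normal(57, 13) on [20, 90].
* M = 2275 outcomes at full scale; per-outcome $\beta_m \sim N(0, .03I)$,
  errors $N(0, .9)$, uniform cluster labels over $c = 6$ clusters, random
  intercepts with SD $\sigma = .2$.
* "Clumpy dependence": two blocks of $M/4$ outcomes each (placed
  deterministically at the start of the outcome index for testability)
  whose intercepts share covariance .07 within a block, sampled through the
  exchangeable-block factorization (shared block factor + idiosyncratic
  term), never a dense $M \times M$ Cholesky.
* Train/test split: all LUAD plus a seeded 70% of CESC train; the CESC
  split is stratified by race by default so small minority groups appear on
  both sides (a plain random split is a flag).

**The non-PSD corner.**  With marginal intercept variance $\sigma^2 < .07$
(true for $\sigma \in \{.1, .2\}$, including the default), a within-block
covariance of .07 is not a valid Gaussian covariance.  The generator clamps
the block covariance to $.99\,\sigma^2$ with a warning; a strict mode
raises instead, and a "correlation" interpretation ($.07\,\sigma^2$) is
selectable.  The default simulation therefore runs with within-block
covariance .0396.

What the generator does **not** emulate: beta-value (0, 1)-scale noise —
simulation operates directly on the standardized M-value scale — probe-level
artifacts, batch effects, or covariate dependence between CNA features.
Passing simulations therefore demonstrate the statistical machinery under
the stated model, not robustness to those real-data features; the
preprocessing module (`mark_boundary_missing`, SD/variance/correlation
filters, `m_value_transform`, `standardize_within_group`) is what carries
real data onto the scale the model assumes.

## Numerical and degenerate-input conventions

Ties in CMMP classification, consensus voting, and nearest-centroid
assignment always resolve to the lowest index.  The correlation filter
always keeps conflict-free features, solves each connected conflict
component exactly (branch-and-bound maximum independent set,
lexicographically smallest maximum set) when the component has at most 30
features, and falls back to a deterministic greedy heuristic
(most-conflicted feature removed first; ties by larger mean |r|, then later
input position) above that — exact search at the scale the variance filter
leaves is typically affordable, and the greedy bound is only needed for
pathological conflict graphs.  Boundary beta values use strict equality.
Filters use the closed threshold ("keep iff SD ≥ .2"), the type-7
linear-interpolation quantile, and absolute correlation (anti-correlated
CNA features are equally redundant; a signed mode would be a one-line
change in `filter_cna`).  Every randomized stage draws its seed from the
master seed via `child_seed()` (a counter-based Lehmer mix), so adding a
stage never perturbs earlier stages, and dataset generation pins the RNG
kind for cross-platform reproducibility.

## Problem sizes used in the shipped checks

The full study design (M = 2275 outcomes, 300 replicates per configuration)
is one flag away, but the shipped tests and the acceptance script run a
desk-scale version chosen so that every qualitative conclusion is already
detectable: M = 100 outcomes with 10 replicates for the naive-MSE check and
30 replicates for the method-ordering, k-robustness, and
under-representation checks; M = 50 with B = 100 for bootstrap
calibration.  At these sizes the whole suite completes in a few minutes on
one core.

## Known limitations

* Matched CMMP only: predicting from covariates alone (no observed
  $y_{nm}$) requires repeated observations per group and is out of scope,
  as are multivariate-outcome CMMP and non-Gaussian random effects.
* One scalar variance component per outcome; no random slopes, crossed
  effects, or heteroskedastic residuals.
* The consensus cluster is a diagnostic; per-outcome assignments are the
  inferential object.
* Real-data preprocessing assumes Infinium-style beta values already
  summarized per probe; IDAT parsing, normalization pipelines, and batch
  correction belong upstream.
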