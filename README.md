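# cmmp: classified mixed model prediction of DNA methylation

DNA methylation data is noisy and scarce, and patients from racial groups
underrepresented in genomic databases are hit hardest: their predictions
are the least reliable.  `cmmp` predicts a patient's *denoised*
methylation — the true mixed effect, free of measurement error — from
genetic (copy-number alteration) and clinical covariates, borrowing
strength from other patients with similar methylation profiles across
cancer types and racial groups.  It is aimed at statistical genomicists
who want smoothed methylation values for downstream analysis, and at
methodologists studying prediction under cohort under-representation.

## The method

1. **Cluster** training samples on their full methylation profile with
   k-means; choose k by the gap statistic (uniform reference, `firstSEmax`
   rule over k = 2..15).
2. **Fit**, independently for each methylation outcome m, a linear mixed
   model with a cluster random intercept

   y_im = x_i β_m + α_{j_i m} + ε_im = θ_im + ε_im,  α_jm ~ N(0, G_m),  ε_im ~ N(0, R_m),

   by REML (profiled to a 1-D search over γ = G/R), where x_i holds CNA
   values, race, age, sex, stage, and cancer type.
3. **Predict** each test observation by matched classified mixed model
   prediction (CMMP): assign the cluster whose BLUP best matches the
   observed residual, Î_m = argmin_j (y_nm − x_n β̂_m − α̂_jm)², and
   predict θ̂_nm = x_n β̂_m + α̂_{Î_m m}.
4. **Estimate real-data MSE** of θ̂_nm by parametric bootstrap
   (regenerate data from the fitted Ĝ, R̂, refit, re-predict).

A full synthetic-cohort generator (n = 655, 65 CNA covariates, 2275
outcomes with "clumpy" cross-outcome intercept covariance, a controllable
White-fraction bias b) and an evaluation harness compare CMMP against the
naive estimate (y itself), OLS regression prediction, and oracle CMMP
(true clusters), under the study's default configuration b = .78, c = 6,
σ = .2.

## Worked example

```r
library(cmmp)

cfg <- simulation_config(n_outcomes = 200)   # desk-scale: 200 of 2275 outcomes
ds  <- suppressWarnings(generate_dataset(cfg, seed = 42))
ds
#> Synthetic methylation dataset: 655 samples x 200 outcomes
#>   581 training / 74 test samples; 6 true clusters; seed 42

res <- run_pipeline(ds, k = 6, seed = 42,
                    modes = c("cmmp", "regression", "naive", "oracle"))
res$fits
#> Per-outcome mixed-model fits: M = 200 outcomes, k = 6 clusters
#>   converged: 200/200; median G_hat = 0.003476, median R_hat = 0.9136
res$metrics
#>       method       mse
#> 1       cmmp 0.1594233
#> 2 regression 0.1651879
#> 3      naive 0.8850748
#> 4     oracle 0.1551274
```

The `mse` column is the mean squared error against the true mixed effect
over all test samples × outcomes.  The naive estimator sits at the error
variance (0.9): using the raw observation buys nothing.  Regression
prediction removes the noise but cannot capture the cluster contribution;
k-means + CMMP recovers part of it and lands between regression and the
oracle bound, exactly the ordering the simulation study is designed to
demonstrate.  (The generator warns that the requested within-block
intercept covariance .07 exceeds σ² = .04 and is clamped — see the methods
vignette.)

For real cohorts, `preprocess_pipeline()` takes paired beta-value and CNA
matrices through boundary-missing handling, SD/variance/correlation
filters, the M-value transform and within-cancer standardization;
`gap_statistic()` selects k; and `bootstrap_mse()` estimates prediction
MSE without access to the truth.  A thin command-line wrapper with
`simulate`, `cluster`, `run`, and `grid` subcommands is installed at
`inst/cli/cmmp`.

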