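# trpsupp

Simulation and latent-variable modelling of **temporal resolution
power** (TRP) and **spatial suppression**, two low-level perceptual
candidates for explaining individual differences in psychometric
intelligence.

The package is for researchers in psychophysics and individual
differences who want to exercise this entire analysis chain without
access to raw participant data: simulated observers complete the full
task battery through the genuine adaptive procedures, and every
statistical claim in the chain — from staircase convergence to the
structural equation models — can be reproduced, stress-tested, and
studied under known generative truth.

## What it implements

**Tasks and procedures.** Simulated observers answer single trials of
four auditory timing tasks (duration discrimination with empty and
filled intervals, temporal generalization, rhythm perception) and a
visual motion-direction task at four stimulus sizes. Measurement uses
the real protocols: a grid-based Bayesian adaptive (QUEST-style)
procedure targeting the 82% point on a log10-duration axis (three
blocks, six estimates per size, drop-extremes averaging), and weighted
up-down staircases targeting 75% (9/3 then 6/2 ms steps; 12/4 ms for
rhythm), reduced to the standard indices: MDD thresholds, the
suppression index `SI = t(7.2°) − t(1.8°)` in log10 units, difference
limina `(x.75 − x.25)/2`, the response-dispersion index, and
z-composite intelligence scores.

**Statistics.** Adjusted-moment descriptives, Pearson correlations
with Fisher-z intervals, repeated-measures ANOVA with Mauchly's test
and Greenhouse–Geisser correction, one-pass 3-SD outlier screening,
upper-half subsample correlations.

**Modelling engine.** A from-scratch maximum-likelihood engine for
structured covariance models
`Σ = Λ(I−B)⁻¹Φ(I−B)⁻ᵀΛ′ + Θ` with fixed/free pattern matrices, box
constraints, analytic gradients, fit indices (CFI/RMSEA/SRMR), AIC,
Satorra–Bentler mean scaling, McDonald's ω, regression factor scores,
and modification indices. The model registry covers the full analysis
chain, including the **fixed-links** decomposition of the four
thresholds into a constant component (loadings 1,1,1,1) and a linearly
increasing suppression component (loadings 0,1,2,3).

## Worked example

Fit the one-factor intelligence model to the published composite
correlations (.51, .46, .39; N = 273) and compute its reliability:

```r
library(trpsupp)
fit <- fit_ml(build_model("g_cfa"), ref_bis_cor(), 273)
round(fit$standardized$lambda[, "g"], 3)
#> bis_capacity    bis_speed   bis_memory
#>        0.776        0.658        0.593
round(omega(fit), 2)
#> [1] 0.72
```

Run the full synthetic study — simulate 273 observers, run every task
through its adaptive procedure, screen outliers, and fit all nine
latent models:

```r
report <- run_study(population_spec(n_subjects = 273, seed = 5),
                    mode = "measure")
report
#> Study report: 273 simulated, 273 analyzed (measure mode, seed 5)
#>   threshold ANOVA: F(1.62, 441.95) = 579.09, GG eps = 0.542
#>   g_cfa              chi2(0) =   0.000, CFI 1.000, RMSEA 0.000, SRMR 0.000, AIC 2184.8
#>   trp_cfa            chi2(2) =   6.166, CFI 0.945, RMSEA 0.088, SRMR 0.038, AIC 3028.2
#>   ss_congeneric      chi2(2) = 127.680, CFI 0.906, RMSEA 0.481, SRMR 0.050, AIC -1712.9
#>   ss_fixedlinks_base chi2(4) =   1.589, CFI 1.000, RMSEA 0.000, SRMR 0.046, AIC -1843.0
#>   ss_fixedlinks      chi2(3) =   1.428, CFI 1.000, RMSEA 0.000, SRMR 0.042, AIC -1841.2
#>   trp_g              chi2(13) =  10.407, CFI 1.000, RMSEA 0.000, SRMR 0.029, AIC 5184.7
#>   ss_g               chi2(13) =   9.497, CFI 1.000, RMSEA 0.000, SRMR 0.039, AIC 338.2
#>   trp_ss_corr        chi2(19) =  19.033, CFI 1.000, RMSEA 0.003, SRMR 0.036, AIC 1165.5
#>   combined           chi2(40) =  31.459, CFI 1.000, RMSEA 0.000, SRMR 0.035, AIC 3323.5

round(report$fits$combined$standardized$beta["g", ], 3)
#>    trp    ssc    ssi      g
#> -0.493 -0.016 -0.015  0.000
```

Read: the thresholds rise with stimulus size (the ANOVA), the
fixed-links decomposition beats the congeneric one-factor model by AIC
(−1841 vs −1713), and in the combined structural model the timing
factor keeps its strong path to g (−.49) while both suppression
components collapse to ≈ 0 — the suppression–intelligence association
is fully carried by shared timing variance, which is the generative
truth of the default population.

## The analysis workflow

The numbered scripts under `analysis/` run the study as a narrative
pipeline, writing tables under `results/`:

```
analysis/01_simulate_population.R   population spec + observer parameters
analysis/02_run_tasks.R             full trial-level battery + outlier screen
analysis/03_descriptives.R          descriptives, RM-ANOVA, correlation matrix
analysis/04_measurement_models.R    CFAs, fixed-links models, MIs, AIC comparison
analysis/05_structural_models.R     latent regressions and the combined model
analysis/06_recovery.R              200-replicate parameter recovery
```

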