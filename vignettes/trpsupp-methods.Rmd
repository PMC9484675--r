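---
title: "Methods: simulated timing and spatial-suppression psychophysics and their latent-variable models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated timing and spatial-suppression psychophysics and their latent-variable models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpsupp)
```

## What the package models

Two experimental traditions link elementary perception to psychometric
intelligence. *Temporal resolution power* (TRP) treats the accuracy of
the brain's interval timing as a latent capacity: performance on
duration discrimination, temporal generalization, and rhythm perception
shares a common factor that correlates substantially with the general
intelligence factor g. *Spatial suppression* describes the rising
presentation time needed to judge the motion direction of a large,
high-contrast grating: the motion-direction discrimination (MDD)
threshold increases with stimulus size, and the size of that increase —
the suppression index (SI) — has been proposed as another low-level
correlate of intelligence.

This package implements the full computational chain needed to study
the interplay of these constructs *in silico*: a generative observer
population with a configurable latent structure, the adaptive
psychophysical procedures that measure each task, the reduction of
trials to the standard performance indices, the descriptive and
correlational statistics, and a structured-covariance modelling engine
that fits every latent model in the chain — confirmatory factor models,
a fixed-links decomposition of the threshold profile, and latent
regressions of g on the timing and suppression factors.

Because no raw data from the motivating study design are publicly
deposited, sample-specific estimates are not reproduction targets.
What the package does reproduce, at desk scale, are (a) worked values
computable from published correlation tables (composite reliabilities,
loadings, confidence intervals), (b) the convergence properties of the
adaptive procedures, and (c) the qualitative pattern of results on
synthetic data generated under matched effect sizes, backed by
parameter-recovery experiments.

## The simulated observer

Each observer is a vector of psychophysical parameters derived from
four correlated standard-normal latent traits:

* `trp` — temporal imprecision (higher = poorer timing),
* `ssc` — the size-*invariant* component of the MDD thresholds,
* `ssi` — the size-*increasing* component (genuine suppression),
* `g` — general intelligence.

The four log10 MDD thresholds follow the fixed-links structure
$$
t_s \;=\; b + \tfrac{\bar{SI}}{3}\,w_s + \sigma_c\,\eta_{ssc}
        + \sigma_i\, w_s\,\eta_{ssi} + \varepsilon_s,
\qquad w = (0,1,2,3),
$$
so that between-subject covariance decomposes exactly into
$\sigma_c^2\,\mathbf{1}\mathbf{1}' + \sigma_i^2\,ww' + \Theta$, the
structure the fixed-links model recovers. Timing-task parameters are
linear in `trp` with standardized loadings, and 18 intelligence subtest
scores (six per composite) load on `g` with per-subtest loadings chosen
so the three composite scores attain their target loadings.

Response generation uses three psychometric families, each anchored so
that the parameter *is* the threshold at the procedure's target level:

* motion direction: a Weibull in log10 duration rising from chance 0.5
  to `1 - lapse`, equal to 0.82 exactly at the observer's threshold;
* duration/rhythm discrimination: a logistic (tanh) in the absolute
  duration difference, equal to 0.75 exactly at the observer's scale;
* temporal generalization: a Gaussian similarity kernel peaked at the
  75 ms standard.

The family for 2AFC motion is the conventional Weibull (the Bayesian
adaptive procedure assumes a parametric family in any case); the
logistic for discrimination and the Gaussian kernel for generalization
are the standard smooth, symmetric choices. The lapse rate defaults to
0.01 — small enough to keep thresholds identifiable, large enough to be
realistic. Latent-to-task mappings are linear on the scale each model
is later fitted on (log10 ms for thresholds), which makes the
generative population exactly the regime the measurement models assume.

### Calibration of the defaults

The generator's defaults are fixed once, from published summary tables
of a validation sample of 273 young adults, and define the study
conditions:

| constant | value | source of the value |
|---|---|---|
| base log threshold | log10(44.69/2.5) ≈ 1.25 | smallest-size mean (display values carry a 2.5 reporting multiplier) |
| mean SI | 0.29 | reported population mean of the index |
| $\sigma_c^2, \sigma_i^2$ | .022, .003 | reported fixed-links latent variances |
| threshold residual SD | 0.05 | reconciles the reported per-size SDs with the latent variances |
| timing base/SD | 18.33/8.22, 8.81/3.26, 55.86/22.43 ms | reported task means and SDs |
| generalization kernel | 6.6 ± 2.0 ms | solved so the expected dispersion index is ≈ .66 |
| timing loadings | .52, .63, .51, .34 | reported loading span .338–.632 |
| composite loadings | .776, .658, .593 | closed-form triad solution of the composite correlations .51/.46/.39 |
| latent correlations | trp–ssc .353, trp–ssi .180, trp–g −.535 | reported structural estimates |

The `g` correlations of `ssc` and `ssi` default to full mediation
through `trp` (−.189 and −.096), which is the generative regime in
which the combined structural model should — and in the tests does —
absorb the suppression–intelligence association into the timing path.
`ssc` and `ssi` are orthogonal, as the fixed-links model assumes.
No individual-level data exist to estimate residual variances, so they
are calibrated to the reported SDs rather than estimated.

## Adaptive procedures

**Bayesian adaptive (QUEST-style) procedure.** A grid posterior over
candidate log10-ms thresholds (uniform prior on
$[\log_{10} 2, \log_{10} 500]$ at 0.01 steps) is updated by the
likelihood of each response under the assumed Weibull family (slope
3.5, chance 0.5, lapse 0.01) anchored at the 82% target. Trial
placement and the final estimate both use the posterior mean; the first
trial is placed at 80 ms. The measurement protocol runs three blocks
with two independent 22-trial runs per stimulus size (44 trials per
size per block, 528 in total); of the six resulting estimates per size
the highest and lowest are discarded and the rest averaged. The prior,
slope, and estimator rule are not dictated by the measured quantity
itself, so they are exposed in `quest_init()`; the packaged defaults
are the canonical ones, and the acceptance checks rely only on the
estimator-robust property that the observer's true percent correct at
the estimate is ≈ 82%.

**Weighted up-down staircases.** Duration discrimination interleaves
two 32-trial series around the 50 ms standard (comparison longer vs
shorter), stepping 9 ms up after an incorrect and 3 ms down after a
correct response for the first six trials and 6/2 ms thereafter; the
step in force is the one belonging to the trial just answered, so the
level of trial 7 is still produced with the 9/3 pair. Each series'
threshold is the mean level over its last twenty trials; on the
comparison scale they give the 25% and 75% points, and the difference
limen is half their distance. The equilibrium percent correct of a
weighted up-down rule is `up/(up+down)` = 75% for all step pairs used.
Levels are floored at 1 ms to avoid non-physical differences.

For rhythm perception, the printed step directions (increase after
correct, decrease after incorrect) cannot converge to a 75% detection
threshold; the implementation therefore uses decrease-4-after-correct /
increase-12-after-incorrect, whose equilibrium is 12/16 = 75%, and
treats the printed direction as a typographical slip. The series start
at a 20 ms deviant, which for observers with large thresholds produces
a mild undershoot within 32 trials — a property of the protocol itself
that the simulation reproduces rather than corrects.

A numerical note on evaluating convergence: over the stationary
distribution of an asymmetric staircase the *expected probability
correct across trials* equals the step-ratio equilibrium exactly, while
the probability evaluated *at the mean level* carries a small
Jensen-gap bias of the order of the psychometric curvature times the
level variance. The convergence checks therefore use observers that are
smooth relative to the step sizes, and additionally assert the
distribution-free form (the observed long-run fraction correct).

## Measure reduction

* **SI** is the difference between the log10 thresholds at the largest
  and smallest size. The thresholds produced by the adaptive procedure
  are already logarithms, so no second logarithm is applied; the
  published index range (−.036 to 1.000) is consistent only with this
  single-log reading.
* **Dispersion index.** The relative "yes" frequency to the standard
  (16 presentations) divided by the sum of relative frequencies over
  all seven durations (8 presentations each for the six alternatives).
  The analyses use an inverted score; any strictly decreasing affine
  map leaves correlation magnitudes unchanged, so the bounded and
  interpretable `1 − index` is used. A session without any "yes"
  response leaves the index undefined; it is flagged and scored at the
  worst value.
* **Outlier screen.** One-sided: subjects exceeding the pre-filter mean
  by three SDs on any of the four timing scores or the smallest-size
  threshold are removed, in a single pass without re-iteration (a
  two-sided switch exists). High values are the poor-performance tail
  on every screened variable.
* **Reporting transform.** Tabled threshold values in ms carry a ×2.5
  display multiplier in the source material; stored thresholds are
  untransformed.

## Descriptive and correlational statistics

`describe()` reports bias-adjusted sample skewness and *excess*
kurtosis (normal = 0), the convention consistent with the published
near-zero values for approximately normal variables. `pearson()`
computes the product-moment correlation with a t-based two-sided p and
a Fisher-z interval (`SE = 1/sqrt(n-3)`); `rm_anova()` implements the
within-subject F from explicit sums of squares with Mauchly's test,
the Greenhouse–Geisser ε from the eigenvalues of the contrast-projected
condition covariance, ε-corrected degrees of freedom, and
Bonferroni-adjusted pairwise paired t tests with `m = k(k-1)/2`. Three
η² variants (total, partial, generalized) are reported side by side
because the flavor behind any single published value is not
identifiable from the value alone; none is used as a reproduction
target. All of these are validated against independent oracles
(direct moment formulas, explicit SS loops, `aov`, `cor.test`).

## The structured-covariance engine

Models are specified as pattern matrices over
$$
\Sigma \;=\; \Lambda (I-B)^{-1} \Phi (I-B)^{-T} \Lambda' + \Theta,
$$
with numeric entries fixed and `NA` entries free, symmetric
$\Phi, \Theta$, latent regressions in $B$, and optional box constraints
per free parameter (used to hold residual variances above zero where a
Heywood case would otherwise occur). Estimation minimizes the
normal-theory discrepancy
$F_{ML} = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p$
by L-BFGS-B with the analytic gradient, parameter scaling derived from
the sample variances (log10-ms and z-scale parameters differ by two
orders of magnitude), a damped Newton polish that drives the projected
gradient below 1e-6, and up to five deterministically seeded jittered
restarts. Perfect-fit recovery, analytic-vs-numeric gradients, and
agreement with an independent generic minimizer of the same objective
(|ΔF| < 1e-8 on random small models) are all under test.

Conventions, chosen once and documented rather than tuned:

* test statistic $T = (n-1) F_{ML}$ (an `n` multiplier is available);
* CFI against the independence baseline (free variances, fitted in
  closed form); RMSEA $=\sqrt{\max(T-df,0)/(df\,(n-1))}$; SRMR over the
  $p(p+1)/2$ unique correlation-metric residuals;
* AIC $= -2\,\mathrm{loglik} + 2q$ with the Wishart-type likelihood, so
  only AIC *differences* are meaningful, and for nested fits they equal
  $\Delta T - 2\,\Delta df$ exactly;
* a saturated model reports CFI 1 and RMSEA 0, flagged;
* standardization divides by model-implied latent and observed SDs;
  for endogenous latents $R^2 = 1 - \psi_{jj}/\mathrm{Var}(\eta_j)$.

Scale invariance holds for free-loading models (standardized solutions
from covariance and correlation input agree to 1e-6) and deliberately
fails for fixed-links models, whose loadings are scale-bound — which is
why those models are always fitted on log10-ms covariances, the only
scale on which latent variances of .022/.003 are interpretable, and why
`run_study()` z-standardizes the timing and composite indicators but
never the thresholds.

The **Satorra–Bentler** mean-scaled statistic is available when raw
data are present: $c = \mathrm{tr}(U\hat\Gamma)/df$ with $\hat\Gamma$
the empirical fourth-moment covariance of the unique elements of $S$
and $U$ the normal-theory residual weight matrix; $T_{SB} = T/c$.
Tests verify $c \to 1$ under normality and $c > 1$ in expectation under
t5 margins. Whether any single published statistic is scaled or raw is
not decidable from the value, so both are reported.

**Modification indices** are univariate score tests: for each fixed
cell, $MI = s^2/(2h)$ with $s$ the gradient of $T$ in that direction at
the solution and $h$ the Schur complement of the direction in the
numerically differentiated Hessian of $T$. A test verifies the MI lands
within 15% of the exact ΔT of an actual refit in a well-conditioned
case and that a planted residual covariance is identified as the
largest index.

**McDonald's ω.** For a one-factor model the standardized congeneric
form $(\sum\lambda)^2 / \big[(\sum\lambda)^2 + \sum\theta\big]$ is
used. For multi-factor models two denominators are available: the
share of unit-weight composite variance attributable to the factor
(default), and a factor-specific denominator that ignores the other
factor's contribution. Published per-factor reliabilities of
fixed-links models are consistent with the factor-specific convention;
since the convention behind them is not stated, both are implemented
and only the one-factor values (identical under every convention) are
treated as reproduction targets.

**Factor scores** use the regression method,
$\widehat\eta = \mathrm{Cov}(\eta, x)\,\Sigma^{-1}(x - \bar x)$ — the
default choice where the extraction method is not prescribed; Bartlett
scoring would only rescale the exactly identified three-indicator case.

## The study pipeline and its model registry

`build_model()` returns the exact pattern matrices for the nine models
of the analysis chain (three one-factor models; the fixed-links
decomposition with and without the free 3.6°–5.4° residual covariance
and the positivity bounds on the first and fourth residual variances;
and four structural models), with degrees of freedom 0, 2, 2, 4, 3,
13, 13, 19, and 40 — each verified exactly in the tests. Endogenous g
is identified by fixing its first composite loading to 1; exogenous
free-loading factors fix their variance to 1 instead.

`run_study()` freezes the stage order — simulate, run tasks, screen
outliers, describe, ANOVA, correlate (with g-factor scores), fit
measurement models, compare AICs, fit structural models — and records
every seed, so a report is byte-reproducible from its specification.
Stage failures are recorded and downstream stages that depend on them
are skipped, never faked.

Two simulation modes exist. `"trial"` runs every adaptive procedure at
full length (about 650 trials per subject; ~25 s for 273 subjects) and
adds realistic measurement noise, which attenuates loadings exactly as
real adaptive estimates would. `"measure"` returns the observer's
generative task parameters directly and is the mode for
parameter-recovery experiments, where the question is whether the
*estimator* is unbiased at the generative values, not whether the
adaptive procedures add noise. `recovery_experiment()` runs 200
replicate populations of 273 subjects in this mode (about 12 s),
refitting the fixed-links variances and the standardized timing-to-g
coefficient; all three are recovered within two Monte-Carlo standard
errors of their generative values.

## What the synthetic data do and do not show

The generator reproduces the *structure* the models assume: linear
latent-to-measure maps, multivariate-normal traits, orthogonal
suppression components, full mediation of the suppression–intelligence
association. Passing tests therefore demonstrate that the procedures
measure what they claim and the estimators recover what generated the
data — not that real observers satisfy those assumptions. In
particular: real threshold distributions are right-skewed and
heavy-tailed (the robust scaled statistic exists for exactly that
reason); real residual structure (the published 3.6°–5.4° residual
correlation) is emulated only when planted; practice and fatigue
effects across blocks are out of scope; and published sample-specific
structural estimates are not reproducible without the raw data, so
they enter only as generative defaults, never as test oracles.

## Problem sizes and determinism

Default problem sizes — 273 subjects, 200 recovery replicates, 500
replicate QUEST runs, 10,500-trial staircase checks — are the package's
chosen desk-scale settings: large enough for the Monte-Carlo standard
errors quoted above, small enough to run interactively. Every
stochastic component consumes the standard R random stream, so a
single `set.seed()` (or the `seed` fields of the specification
objects) reproduces any result bit for bit; internal restarts preserve
the caller's stream.
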