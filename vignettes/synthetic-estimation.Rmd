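---
title: "Regression synthetic estimation of area-level prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression synthetic estimation of area-level prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthprev)
```

## The problem

Health-service planners need prevalence estimates of quantities such as
perceived and unmet mental health need at the level of provinces and
subprovincial health regions, but population health surveys rarely carry
enough respondents per region to estimate these directly with useful
precision, and the outcome items are not administered every year. Regression
synthetic estimation addresses both gaps: an individual-level prediction
model is developed once on survey microdata, and area-level prevalences are
then forecast from the area's *predictor profile* alone — quantities that
administrative and census sources can supply even in years when the outcome
is not measured.

## The model

Respondents $i$ are nested in health regions $a$. The individual-level model
is a random-intercept binary logistic regression

$$\Pr(y_{ia} = 1 \mid x_{ia}, u_a) = \operatorname{expit}\!\big(\beta_0 + x_{ia}^\top \beta + u_a\big),
\qquad u_a \sim \mathcal N(0, \sigma_u^2),$$

fitted by maximum marginal likelihood with adaptive Gauss–Hermite
quadrature (`fit_random_intercept_logit()`, default 9 nodes; one node is the
Laplace approximation). Starting values come from the $\sigma_u = 0$
iteratively-reweighted-least-squares fit (`fit_logistic()`, convergence when
the relative log-likelihood change falls below $10^{-10}$ or after 100
iterations). The full model is reduced by backward elimination on AIC or BIC
(`backward_select()`): at each step the single term whose removal most
decreases the criterion is dropped — categorical variables as whole dummy
blocks — stopping when no removal decreases it.

Model adequacy is summarized by the weighted C statistic (the probability
that a randomly chosen case is ranked above a randomly chosen non-case,
equal to the area under the weighted ROC curve), the calibration slope (the
slope of a logistic regression of the outcome on the logit of predicted
risk; 1 is ideal, below 1 overconfident, above 1 underconfident) and a
decile calibration table of mean predicted risk against observed event
fraction by weighted risk decile.

## Synthetic estimation

The synthetic step converts the individual model into area estimates. For
area $a$, compute the design-weighted proportion of each non-reference
categorical level and the weighted mean of each continuous term — the
"parallel set of predictors on the area level" (`area_profile()`; the
profile is literally the weighted column mean of the fixed-effect design
matrix, so dummy coding and interactions match the model exactly). The
coefficients are applied to the profile,

$$\eta_a = \beta_0 + \sum_j \beta_j \, \bar x_{aj}, \qquad
\hat p_a^{\text{synth}} = 100 \cdot \operatorname{expit}(\eta_a),$$

with the random intercept set to zero (`synthetic_estimate()`). Validation
compares predicted against observed design-weighted proportions per area;
the metric is the signed difference `predicted - observed` in percentage
points (`absolute_difference()`, `validate_model()`), rounded to two
decimals only at serialization.

### The aggregation (Jensen) gap

Because `expit` is nonlinear, applying it to aggregated predictors is not
the same as aggregating individual predictions. The package exposes both
estimators: the marginal-profile synthetic estimator above (the method's
defining convention, and the default output) and the individual-aggregation
oracle $100 \sum_i w_i \operatorname{expit}(\eta_i) / \sum_i w_i$
(`individual_aggregation_estimate()`). On an area whose respondents share a
single covariate pattern the two coincide exactly; under within-area
heterogeneity they differ, the oracle tracks the observed proportion, and
the difference quantifies how much of a validation discrepancy is inherent
to the marginal convention rather than to model misfit. The acceptance
script reports this gap on a deliberately heterogeneous simulation, where it
reaches several percentage points; users validating against observed data
should inspect both columns before attributing error to the coefficients.

A related but smaller effect comes from setting $u_a = 0$: with
$\sigma_u > 0$ the population-average prevalence exceeds
$\operatorname{expit}$ at the median region slightly. We keep $u = 0$
because external-validation areas (new years, newly scored regions) have no
estimated intercept; for development-data areas `validate_model(use_blup =
TRUE)` adds the empirical-Bayes intercept instead.

## Survey weighting

Observed proportions, area profiles and performance metrics use the survey
design weights throughout; proportions are kept on the percent scale.
Variance estimation uses bootstrap replicate weights: a statistic is
recomputed under every replicate column and the SE is
$\sqrt{B^{-1} \sum_b (\hat\theta_b - \hat\theta)^2}$ with deviations taken
from the full-sample estimate, matching the mean-bootstrap convention of
survey-agency replicate weights (`bootstrap_se()`).

Whether the *individual-level model* should be weight-fitted is genuinely
open — information criteria are ill-defined under raw expansion weights — so
the default is unweighted fitting with a `use_weights` option that
normalizes weights to mean 1 and treats them as pseudo-likelihood weights;
`n` in the BIC is always the respondent count. Both routes are exercised in
the test suite.

## The simulator

`default_sim_config()` defines the study conditions the package is tested
under: ten provinces in three modelling regions (Atlantic, Central,
Western), 29 health regions, and the common categorical predictor block of
perceived-need modelling — sex, age group, self-reported mental health,
diagnosed mood/anxiety disorder, life stress, life satisfaction. True
coefficients were fixed once so that national prevalences sit near 18%
(perceived) and 3.9% (unmet) with plausible effect directions; provinces
differ modestly in mental-health status and stress distributions so area
prevalences genuinely vary; the area random-intercept SD defaults to 0.25
on the log-odds scale. Design weights are lognormal
("inclusion-probability proxy" times noise, $\sigma_{\log} = 0.4$)
normalized to mean 1 per province. Replicate weights follow the Rao–Wu–Yue
rescaled cluster bootstrap over synthetic dwelling clusters (default 10
respondents): within a province with $n_h$ clusters each replicate draws
$n_h - 1$ clusters with replacement and rescales by $n_h/(n_h-1)$, so a
single-cluster stratum keeps its design weights.

What the simulator does *not* emulate: the real two-frame sampling design
(area frame plus child-benefit list frame), nonresponse and calibration
adjustments, item missingness patterns, postal-code linkage of
neighbourhood deprivation (simulated here as an ordinary area-level
categorical when needed), and the true joint distribution of predictors.
Passing tests therefore demonstrate the correctness of the estimation
machinery under a known generative process, not the accuracy of any
particular published estimate, which requires restricted survey microdata.

## Numerical choices

* Quadrature: adaptive Gauss–Hermite with 9 nodes by default; the suite
  checks that 25 nodes moves the log-likelihood by less than $10^{-3}$ on a
  recovery dataset.
* A boundary fit $\sigma_u \to 0$ is returned with `boundary = TRUE`, not
  treated as an error; the log-likelihood never falls below the nested
  $\sigma_u = 0$ fit.
* Separation raises a classed `fit_error` (detected from extreme fitted
  probabilities together with runaway coefficients); rank deficiency raises
  a `design_matrix_error` naming the aliased columns; rows with missing
  model variables are dropped with a logged count.
* Backward-selection ties (criteria within $10^{-9}$) remove the term later
  in the declared term order — a documented, deterministic rule.
* Decile assignment sorts by risk with ties kept in row order and places a
  row in the decile containing the midpoint of its weight interval, so the
  ten groups partition the sample exactly and weight shares sum to 1.
* The C statistic uses one sort plus tie-group accumulation; a brute-force
  pair enumeration oracle in the tests confirms exact equality, including
  under ties and weights.
* The SE of $\sigma_u$ (used for parameter-recovery checks) comes from a
  numerical Hessian of the marginal deviance over $(\theta, \beta)$, since
  the mixed-model machinery conditions its covariance on $\theta$.
* All randomness flows from one master seed; pipeline stages derive
  label-stable sub-seeds, so removing a validation dataset from a run
  configuration leaves every development artifact byte-identical.

## Problem sizes

The test suite and acceptance script use desk-scale replicas of the study
design: about 29,000 respondents per simulated survey year (1,000 per health
region) for the national pipeline, 30 areas of 500 for random-intercept
parameter recovery, 10 areas of 2,000 for synthetic-estimation recovery,
n = 10,000 across 20 seeds for selection behaviour, and n = 50,000–100,000
for distributional limit checks. These sizes were chosen so Monte-Carlo
error is small relative to every stated tolerance.

## Known limitations

* Only a scalar random intercept is supported — no random slopes or crossed
  effects, no multiple imputation.
* Backward selection removes categorical variables as blocks; level-wise
  merging is out of scope. Interaction terms may be declared but are not
  screened automatically.
* No composite or EBLUP-style small-area estimators: the package implements
  the regression synthetic estimator plus its individual-aggregation
  oracle, deliberately.
* Bootstrap SEs are provided as an extension; published
  observed-versus-predicted tables of this method typically omit them.

## A short worked run

```{r, eval = FALSE}
cfg <- default_run_config(seed = 1, n_per_area = 500)
res <- run_pipeline(cfg, out_dir = "run1")
head(res$report)
```

The output directory contains fitted-model JSONs, performance reports,
per-dataset estimate CSVs, a consolidated `report.csv`/`report.md` in the
observed/predicted/difference layout, and a reproducibility manifest.
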