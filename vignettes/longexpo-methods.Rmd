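---
title: "Modelling repeated exposure biomarkers against a binary outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling repeated exposure biomarkers against a binary outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longexpo)
```

## The problem

Environmental epidemiology often measures an exposure biomarker — here the
motivating case is urinary phthalate metabolites collected at up to four
prenatal visits — repeatedly and irregularly across pregnancy, and asks how
that longitudinal exposure relates to a binary, non-time-varying outcome
such as preterm birth (delivery before 37 completed weeks). The data
structure is the mirror image of the usual longitudinal setting: the
*predictor* is the repeated, correlated process, while the outcome is a
single Bernoulli variable per subject, so generalized linear mixed models
for correlated outcomes do not apply directly.

Writing $Y_i$ for the outcome, $X_{ij}$ for the ln-transformed exposure of
subject $i$ at visit $j$ (time $t_{ij}$, gestational days internally,
reported in weeks), and $Z_{ij}$, $W_i$ for time-varying and baseline
covariates, an association can arise through at least four mechanisms: a
sensitive window (only $X$ at one period matters), a generally elevated
average, an acute spike, or a temporal trend. No single regression captures
all four, which is why the package implements nine complementary
strategies behind one uniform result contract, plus a synthetic-cohort
generator and a simulation harness that measures each strategy's operating
characteristics under each mechanism.

## The nine strategies

1. **Simultaneous multiple logistic regression**
   (`multiple_logistic_model()`): $\mathrm{logit}\,P(Y_i=1) = \beta_0 +
   \sum_j \beta_j X_{ij} + \gamma' Z_i + \eta' W_i$. Complete-case only;
   between-visit collinearity inflates standard errors.
2. **Shrinkage (MAP) variant** (`bayes = TRUE`): the visit-coefficient
   block gets a mean-zero Gaussian prior with covariance
   $\tau^2 R(\rho)$, $R$ an AR(1) correlation over visit order, so
   temporally adjacent coefficients are shrunk toward each other and
   toward zero. $(\tau^2, \rho)$ are fixed or chosen on a small grid by
   the Laplace-approximate marginal likelihood.
3. **Parallel cross-sectional models** (`cross_sectional_models()`): one
   logistic fit per visit, optional Bonferroni correction, plus a pooled
   GEE (`fit_pooled_gee()`) whose fully visit-stratified mean model under
   working independence reproduces the separate fits exactly and supplies
   the Wald test of $H_0: \beta_1 = \dots = \beta_n$ on a
   subject-clustered sandwich covariance.
4. **Subject-mean summary** (`mean_summary_model()`): the arithmetic mean
   of ln values (the ln geometric mean concentration) per subject;
   time-varying covariates are averaged (binary time-of-day becomes a
   proportion).
5. **Subject-maximum summary** (`max_summary_model()`): the largest ln
   value, covariates taken from the argmax visit, ties broken by the
   earliest visit.
6. **Two-stage mixed model** (`two_stage_blup_model()`,
   `two_stage_cluster_model()`): Stage 1 fits
   $X_{ij} = \alpha_0 + \alpha_1 t_{ij} + a_{0i} + a_{1i} t_{ij} +
   \gamma' Z_{ij} + \varepsilon_{ij}$ by REML with bivariate-normal
   random effects; Stage 2 is a logistic model on the BLUPs
   $(\hat a_{0i}, \hat a_{1i})$, or on a k-means clustering of the
   standardized BLUP plane.
7. **Trajectory contrast** (`trajectory_contrast()`): the reverse-temporal
   additive mixed model $X_{ij} = b_{0i} + f_1(t_{ij}) + Y_i f_2(t_{ij})
   + \eta' Z_{ij} + \varepsilon_{ij}$ with penalized cubic regression
   splines; descriptive only — risk is never estimated from it.
8. **Clustering of exposure profiles**: a full-covariance Gaussian
   mixture on complete exposure vectors with BIC selection
   (`gmm_cluster()`), and functional k-means on per-subject lines
   evaluated on a grid (`functional_cluster()`, balance not required),
   each followed by `cluster_association()` (chi-square with $K-1$ df and
   a logistic model on cluster indicators).
9. **Functional logistic regression** (`fpca_pace()`,
   `functional_logistic_model()`): sparse FPCA with conditional-
   expectation scores, a logistic model on the leading $L$ scores, the
   time-varying coefficient $\beta(t) = \sum_l \beta_l \phi_l(t)$, and a
   global $L$-df likelihood-ratio test.

## What the synthetic cohort emulates

`make_scenario("phthalate_like")` encodes the structure of the motivating
study: 480 subjects; four visits at median gestational weeks 9.79, 17.9,
26.0 and 35.1 with the printed ranges (times drawn uniformly within each
range, the least-informative choice consistent with a median and a range,
then sorted within subject because adjacent windows overlap slightly);
ln-normal exposure with total variance 1.0 split to hit a target ICC
(0.30 by default, 0.57 as the stable-biomarker reference); urinary
specific gravity as Normal(1.015, 0.005^2) truncated to [1.000, 1.040]
and a Bernoulli(0.5) afternoon-collection indicator as time-varying
covariates (physiologic defaults, configurable — the source study prints
no distributions); a baseline log-odds targeting a 130/482 case
fraction; and outcome-dependent loss of the final visit (cases 55%,
controls 10%, chosen to reproduce the observed visit-4 attrition from
479/422/412 down to 380 available samples, concentrated among cases who
had already delivered). The outcome is drawn prospectively from a
logistic model even though the emulated design is a nested case-control:
odds ratios from unweighted logistic fits are invariant to
outcome-dependent sampling, which is also how the motivating study
analyzed its data.

Four effect mechanisms are available — `mean`, `window`, `acute`,
`slope` — each adding `effect_size` times the (cohort-centred) effect
feature to the linear predictor. Centring keeps the case fraction at its
target across mechanisms without changing the coefficient being
recovered. The feature is computed on the full pre-dropout visit set, so
dropout attenuates, rather than redefines, the estimand. The slope
scenarios disable dropout: case-only loss of the final visit mechanically
couples the observed subject mean to the random slope and would blur the
mechanism the scenario is meant to isolate.

What the generator does *not* emulate: limits of detection, multiple
correlated pollutants, missingness at interior visits, skewness beyond
lognormality, and real covariate-exposure confounding structure (a single
`confounding_strength` hook ties specific gravity to the outcome).
Passing tests therefore demonstrate internal statistical correctness
under a faithful but idealized data-generating process, not performance
on any particular real cohort.

## Numerical and design choices

* **Time** is stored in gestational days, modelled in weeks centred at
  the cohort mean, so design matrices are well scaled and the random
  slope has ln-units-per-week meaning.
* **Missing visits are absent rows.** No imputation anywhere; each
  strategy applies its own inclusion rule and reports `n_used`, which is
  why the strategies legitimately disagree on sample size.
* **Logistic fitting** is explicit IRLS (deviance tolerance `1e-11`, 100
  iterations) so the deviance trace is testable and separation is
  flagged (standardized coefficient above 10, configurable) instead of
  silently returned; `stats::glm` serves as an independent cross-check in
  the tests, and the 2x2 closed form as an oracle.
* **MAP logistic** uses damped Newton steps on the penalized
  log-likelihood; the posterior covariance is the Laplace approximation.
  The grid for $(\tau^2, \rho)$ is {0.01, 0.1, 1, 10} x {0, 0.3, 0.6,
  0.9}; AR(1) distance is integer visit order, not continuous time.
* **ICC** comes from a random-intercept-only REML fit; its CI is a
  subject-level nonparametric bootstrap (B = 500 by default), clipped to
  bracket the point estimate, since small-B percentile intervals need
  not contain it. Pairwise visit correlations use pairwise-complete
  subjects. Whether to compute the ICC on dilution-adjusted values is
  left to the caller via `residualize_exposure()` (default: unadjusted).
* **Two-stage demotion.** The random slope is dropped when the fit is
  singular, |intercept-slope correlation| > 0.95, or a REML
  likelihood-ratio comparison against the intercept-only model falls
  below the 95% $\chi^2_2$ critical value. The pure correlation/boundary
  triggers proved insufficient: REML routinely returns tiny positive
  slope variances without a boundary flag. BLUPs are standardized before
  k-means because intercepts and slopes differ by orders of magnitude.
  Stage-2 standard errors ignore Stage-1 uncertainty by construction;
  the harness measures the consequences instead of hiding them.
* **Trajectory contrast.** The difference term is a constant offset plus
  a penalized difference smooth (basis dimension 8, REML smoothing with a
  1.5 penalty inflation so a pure constant offset is not awarded spurious
  wiggle). `edf_difference` = 1 + the smooth's EDF: near 1 means a
  constant gap, near 2 a linear divergence, and forcing the smoothing
  parameter to infinity collapses it to 2 exactly. The headline
  interaction test deliberately does **not** reuse the penalized fit: an
  approximate test whose df is the rounded EDF of the same fit was
  anti-conservative in null calibration, so the test is a Wald test of
  the whole group block from a companion fit with an *unpenalized*
  difference spline (fixed df = basis dimension), a construction whose
  level does not depend on an estimated EDF. The linear-slope test comes
  from a second companion model whose difference is constant + linear
  only.
* **Gaussian mixture.** Full unstructured covariances, EM from seeded
  k-means initializations, relative log-likelihood tolerance `1e-6`, BIC
  in the larger-is-better convention $2\ell - m\log N$ (stated because
  both sign conventions circulate). A diagonal ridge proportional to
  tr(S)/d engages only when a component covariance is numerically
  singular; a component collapsing below d+1 effective points stops the
  iteration at the last healthy state. Cluster labels are ordered by
  ascending overall mean so odds ratios have a stable reference.
* **Functional clustering** reduces each subject to a least-squares line
  (a constant for single-visit subjects): with at most four irregular
  points per subject, any richer basis is unidentifiable. Grid size 20.
* **Sparse FPCA.** Mean and covariance by penalized spline smoothing
  (surface basis capped at 8 per margin); eigenanalysis under trapezoid
  quadrature; eigenfunction signs fixed by positive integral. The noise
  variance is the central-half gap between the smoothed diagonal and the
  surface diagonal, floored at zero — and because a four-visit design
  makes the surface diagonal an extrapolation, a zero floor falls back
  to the profile MLE of $\sigma^2$ under the fitted eigenstructure
  (`noise_source` records which estimator was used). Model selection
  offers a ten-fold approximation to leave-one-curve-out CV (exact LOCV
  is O(N) refits) and a "modified BIC": the pooled Gaussian marginal
  log-likelihood with the noise variance profiled per candidate L,
  penalized by half the free-parameter count times log total
  observations. The two-step fit (scores, then logistic regression) is
  implemented and labelled as such; the plug-in band on $\beta(t)$
  ignores FPCA uncertainty and says so in its notes.
* **Simulation harness.** Headline tests per strategy are fixed (see
  `headline_tests()`); clusterings run at fixed K = 2 in the harness so
  the chi-square df is stable across replicates. Per-replicate results
  can stream to CSV for resumability. Type-I calibration in the test
  suite uses 400 replicates for the fast strategies and 200 for the
  trajectory model, with acceptance bands of about two Monte Carlo
  standard errors; parameter-recovery and power comparisons use
  N = 2000-4000 with 120-150 replicates. These sizes were fixed from
  per-replicate timings before the calibration was run.

## Known limitations

Stage-wise methods (two-stage BLUPs, both clusterings) understate
uncertainty because first-stage estimation error never reaches the
second stage. The GEE equality test relies on large-sample sandwich
behaviour (480 clusters is comfortable; a few dozen would not be). The
functional methods are honest about sparse designs: with four points per
curve the covariance surface, and hence eigenfunctions beyond the second,
are weakly identified. The MAP prior acts on visit order, so unequal
visit spacing is not reflected in the prior correlation. None of the
models addresses informative dropout beyond the generator's explicit MAR
mechanism; inverse-probability weighting is out of scope by design.

## A worked example

```{r example, eval = FALSE}
library(longexpo)

scenario <- make_scenario("phthalate_like", icc_target = 0.30)
cohort <- simulate_cohort(scenario, seed = 1)
truth_check(cohort)

cohort_icc(cohort, B = 200, seed = 1)
visit_correlations(cohort)

comparison <- compare_methods(cohort, seed = 1)
comparison$summary
tidy(comparison)

oc <- simulation_study(
  list(null = make_scenario("phthalate_like"),
       mean = make_scenario("phthalate_like", effect_type = "mean",
                            effect_size = 0.3)),
  methods = c("mean_wald", "max_wald", "gee_equality"),
  reps = 200, seed = 1
)
oc
```
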